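Package: cytocnv
Title: Consensus CNV Calling and Cytoband Burden Association with
    Gray-Matter Networks
Version: 0.1.0
Authors@R:
    person("Mind", "Imaging Genetics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale imaging-genetics pipeline linking cytoband-level
    copy-number-variant (CNV) burden to gray-matter-concentration (GMC)
    brain networks. Implements conservative consensus CNV calling from
    SNP-array Log R Ratio / B-allele-frequency tracks (GC-wave correction,
    circular binary segmentation, a five-state copy-number hidden Markov
    model, consensus fusion, SNR and structural filters), genome-wide and
    per-cytoband burden statistics with two-stage case/control screening,
    source-based morphometry (MDL order selection plus infomax ICA) of
    subject-by-voxel GMC matrices, and covariate-adjusted association of
    network loadings with CNV features. Ships a synthetic-data generator
    with planted ground truth so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
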