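# cytocnv

Consensus CNV calling and cytoband-burden association with gray-matter
brain networks, at desk scale and fully testable offline.

## The problem

Copy-number variants (CNVs) are deletions (copy number 0 or 1) or
insertions (copy number >= 3) of DNA segments. Individually, small CNVs
are too rare and too weak to explain much disease risk; collectively, the
CNVs falling in one cytogenetic band may share biology. This package
implements a pipeline for the hypothesis that *band-level CNV burden* is
(a) enriched in a patient group and (b) associated with structural brain
phenotype — specifically, the subject loadings of gray-matter
concentration (GMC) networks obtained by spatial ICA (source-based
morphometry).

It is aimed at methodologists who want a transparent, self-contained
re-implementation of this analysis style: every stage is exercised on
synthetic data with planted ground truth, and every algorithmic step
(CBS, the copy-number HMM, consensus fusion, MDL order selection, infomax
ICA) is implemented in the package rather than wrapped.

## The model

**Calling.** Per sample, the Log R Ratio track is corrected (winsorize,
remove wave-dominated principal components and the per-sample GC-track
fit, median-centre), QC'd (pass iff LRR SD < 0.28), then segmented twice:

* CBS: recursive circular binary segmentation; a split at arc `(i, j]` is
  accepted iff the permutation p of
  `T = |mean(arc) - mean(rest)| / (sigma * sqrt(1/k + 1/(n-k)))`
  is <= 0.01;
* HMM: five states (copy numbers 0-4), Normal LRR emissions, BAF
  genotype-cluster emissions, distance-dependent transitions
  `p_change(d) = p_base * (1 - exp(-d/D))`, Viterbi decoding.

Only segments found by both (>= 3 markers, overlapping or < 3 markers
apart) become calls, which must then pass a flank-standardized SNR check
(`>= 2`), a 500-bp size floor (homozygous deletions excepted) and
telomere/centromere overlap filters. Calls merge across samples into
regions; regions carried by < 1% of subjects are *rare*.

**Association.** Per-subject, per-band counts of CNVs/deletions/insertions
are screened in two stages (pooled t, p < 0.01 on all subjects; same-sign
p < 0.05 in the White stratum). GMC matrices are decomposed as `X = A S`
(infomax ICA, order by MDL); each network's loadings are regressed on
age, gender, site dummies and a screened CNV feature, Bonferroni-corrected
over `networks x features`; deletion-load groups (0/1/2 deletions in the
band) are compared by one-way ANOVA with percent loading reductions.

## Worked example

```r
library(cytocnv)
rep <- run_pipeline(default_run_config(seed = 4))
print(rep)
```

```
cytocnv pipeline report
  subjects: 60 (QC pass 58) | planted events: 57
  final calls: 44 in 15 regions
  screening: 2 features selected
  ICA: k = 5, variance explained 0.9121
  top association: component 5 ~ 2q5.1:cnv (p = 3.58e-08, dR2 = 0.417)
  call recovery: sensitivity 0.83, precision 1.00
```

Reading this: 60 synthetic subjects were simulated with case-enriched
deletions planted in band 2q5.1 and a matched loading reduction planted on
one GMC component. The caller recovered 83% of the planted events
(>= 10 markers, 50% reciprocal overlap) with no false calls; two-stage
screening selected the 2q5.1 CNV and deletion features; ICA chose k = 5 by
MDL; and the top covariate-adjusted association links the 2q5.1 feature to
the ICA component that matches the planted deletion-effect source, far
below the Bonferroni threshold (0.05 / (5 x 2) = 5e-3). Per-seed numbers
vary; the acceptance suite quantifies the distribution over seeds.

Single stages are exported too (`cbs_segment`, `hmm_segment`,
`consensus_calls`, `screen_cytobands`, `infomax_ica`,
`regress_loading_on_feature`, ...), and a CLI wraps them:

```sh
Rscript -e 'cytocnv::cytocnv_cli()' simulate --config cfg.yaml --out sim/
Rscript -e 'cytocnv::cytocnv_cli()' call --signals sim/signals \
    --markers sim/markers.tsv --cytoband sim/cytoBand.txt --out calls/
Rscript -e 'cytocnv::cytocnv_cli()' run-all --config cfg.yaml --out out/
```

Signal files use the PennCNV tab-separated dialect
(`Name Chr Position  Log R Ratio  B Allele Freq`), cytoband maps the UCSC
`cytoBand.txt` dialect (0-based half-open, converted to 1-based
internally), calls a BED-like TSV.

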