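#' Default desk-scale run configuration
#'
#' A full end-to-end configuration: a 2-chromosome, ~2,500-marker map, a
#' 60-subject cohort, a designated effect band receiving case-enriched
#' deletions, and a 5-component GMC mixing model with a deletion-load
#' effect. Event rates and effect sizes are the paper-scale world rescaled
#' to desk scale by power analysis: the stage-1 screening t-statistic, not
#' the carrier count, is what survives downscaling (t is proportional to
#' the group difference times sqrt(n)), so effect-band rates are set to
#' keep the planted feature in the p ~ 1e-3 screening regime at n = 60;
#' the per-copy loading reduction is scaled by sqrt(301/60) for the same
#' reason; and event sizes are enlarged so events span ~10-25 markers at
#' this map's uniform density (real arrays concentrate probes inside CNV
#' regions; a uniform desk map cannot).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param ... named overrides merged into the default list (nested lists
#'   are merged recursively).
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    map = list(n_chrom = 2L, markers_per_band = 80L, bands_per_chrom = 16L,
               band_bp = 1e6, tel_bp = 5e4, cen_bp = 1e5),
    cohort = list(n_case = 30L, n_control = 30L),
    planting = list(background_rate = 0.01, effect_band = "2q5.1",
                    case_rate = 0.8, control_rate = 0.2,
                    second_deletion_rate = 0.4,
                    size_range = c(1.25e5, 3e5),
                    hom_del_prob = 0.05, del_frac = 0.9, cn4_frac = 0.5),
    array = list(wave_amplitude = 0.3),
    caller = list(alpha = 0.01, n_perm = 200L, min_markers = 3L,
                  prune_tol = 0.05, max_gap_markers = 3L,
                  cbs_mean_threshold = 0.1, flank_markers = 40L,
                  snr_threshold = 2, min_bp = 500,
                  max_tel_cen_overlap = 0.5, cn0_exception = TRUE,
                  qc_sd = 0.28, k_sd = 3, rare_frequency = 0.01),
    screening = list(p1 = 0.01, p2 = 0.05),
    gmc = list(n_components = 5L, n_voxels = 1500L, k = "mdl",
               mdl_stride = 3L, deletion_fraction = 0.25,
               diag_effect = -0.5, noise_sd = 0.3,
               diagnosis_component = 1L, deletion_component = 2L),
    assoc = list(alpha = 0.05))
  dots <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_rec(cfg, dots), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Values in the file override the defaults of [default_run_config()].
#' @param path `.yaml`/`.yml` (requires the `yaml` package) or `.json`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_arg("the 'yaml' package is required for YAML configs")
    yaml::yaml.load_file(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_run_config, c(list(seed = over$seed %||% 1L),
                                over[setdiff(names(over), "seed")]))
}

# derive a stage seed from the master seed (kept below 2^31)
stage_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 2147483587L

#' Consensus-call one sample on one chromosome
#'
#' Convenience wrapper running CBS, the HMM, consensus fusion and the SNR
#' filter on a single chromosome track.
#' @param lrr,baf,positions chromosome track.
#' @param caller caller sub-configuration (see [default_run_config()]).
#' @param seed RNG seed for the CBS permutations.
#' @export
call_chromosome <- function(lrr, baf, positions, caller, seed = 1L) {
  cbs <- cbs_segment(lrr, positions, alpha = caller$alpha,
                     n_perm = caller$n_perm,
                     min_markers = caller$min_markers, seed = seed,
                     prune_tol = caller$prune_tol)
  hmm <- hmm_segment(lrr, baf, positions)
  cand <- consensus_calls(cbs, hmm, positions,
                          max_gap_markers = caller$max_gap_markers,
                          cbs_mean_threshold = caller$cbs_mean_threshold,
                          min_markers = caller$min_markers)
  snr_filter(cand, lrr, flank_markers = caller$flank_markers,
             snr_threshold = caller$snr_threshold)
}

#' Run the full pipeline on synthetic data
#'
#' Simulate (map, cohort, planted CNVs, arrays, GMC) -> correct & QC ->
#' consensus-call -> burden & screening -> ICA -> association, with
#' stage-level counts and ground-truth evaluation collected in a report.
#' The run is a pure function of the configuration.
#'
#' @param config a `run_config` from [default_run_config()].
#' @param verbose emit per-stage messages.
#' @return a `cytocnv_report` list.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  log_counts <- list()
  seed <- config$seed
  mm <- do.call(generate_marker_map,
                c(config$map, list(seed = stage_seed(seed, 1L))))
  markers <- mm$markers; cyto <- mm$cytobands
  say("map: %d markers, %d bands", nrow(markers), nrow(cyto$bands))

  subjects <- generate_cohort(config$cohort$n_case, config$cohort$n_control,
                              seed = stage_seed(seed, 2L))
  pl <- do.call(planting_config, config$planting)
  truth <- plant_cnvs(subjects, cyto, pl, seed = stage_seed(seed, 3L))
  say("planted %d events", nrow(truth))

  n <- nrow(subjects)
  lrr <- matrix(NA_real_, n, nrow(markers),
                dimnames = list(subjects$subject_id, markers$marker_id))
  baf <- lrr
  for (i in seq_len(n)) {
    arr <- simulate_array(subjects$subject_id[i], markers, truth,
                          wave_amplitude = config$array$wave_amplitude,
                          seed = stage_seed(seed, 100L + i))
    lrr[i, ] <- arr$lrr; baf[i, ] <- arr$baf
  }
  corrected <- correct_lrr(lrr, markers$gc)
  qc <- qc_samples(corrected, config$caller$qc_sd)
  log_counts$qc_failed <- sum(!qc)
  say("QC: %d/%d pass", sum(qc), n)
  keep_ids <- subjects$subject_id[qc]

  caller <- config$caller
  calls <- list()
  for (sid in keep_ids) {
    for (ch in unique(markers$chrom)) {
      sel <- markers$chrom == ch
      cc <- call_chromosome(corrected[sid, sel], baf[sid, sel],
                            markers$pos[sel], caller,
                            seed = stage_seed(seed, 1000L + length(calls)))
      if (nrow(cc)) {
        cc$subject_id <- sid; cc$chrom <- ch
        calls[[length(calls) + 1L]] <- cc
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(subject_id = character(0), chrom = character(0),
               first = integer(0), last = integer(0), start = numeric(0),
               end = numeric(0), n_markers = integer(0),
               copy_number = integer(0), class = character(0),
               snr = numeric(0))
  log_counts$candidates <- nrow(calls)
  calls <- structural_filters(calls, cyto, min_bp = caller$min_bp,
                              max_tel_cen_overlap = caller$max_tel_cen_overlap,
                              cn0_exception = caller$cn0_exception)
  log_counts$after_structural <- nrow(calls)
  excl <- exclude_outlier_samples(calls, keep_ids, caller$k_sd)
  calls <- calls[calls$subject_id %in% excl$retained, , drop = FALSE]
  log_counts$retained_subjects <- length(excl$retained)
  say("calls: %d across %d subjects", nrow(calls),
      length(excl$retained))

  reg <- define_regions(calls, length(excl$retained),
                        max_gap_markers = caller$max_gap_markers,
                        rare_frequency = caller$rare_frequency)
  calls <- reg$calls
  subj_kept <- subjects[subjects$subject_id %in% excl$retained, ]
  burden <- compute_burden(calls, subj_kept$subject_id)
  burden_tests <- lapply(
    c("total_cnvs", "total_deletions", "total_rare_cnvs",
      "total_rare_deletions"),
    function(m) {
      x <- burden[[m]]
      t_all <- two_sample_t(x, subj_kept$diagnosis)
      aa <- ifelse(subj_kept$ethnicity == "AA", "case", "control")
      t_aa <- two_sample_t(x, aa)
      adj <- ancova_f(x, subj_kept$diagnosis,
                      subj_kept[, c("ethnicity", "tissue")])
      data.frame(metric = m, t = t_all[["t"]], p = t_all[["p"]],
                 t_aa = t_aa[["t"]], p_aa = t_aa[["p"]],
                 F_adj = adj[["F"]], p_adj = adj[["p"]])
    })
  burden_tests <- do.call(rbind, burden_tests)

  feats <- cytoband_features(calls, cyto, subj_kept$subject_id)
  screen <- screen_cytobands(feats, subj_kept$diagnosis,
                             subj_kept$ethnicity == "White",
                             p1 = config$screening$p1,
                             p2 = config$screening$p2)
  sel_feats <- screen$feature[screen$selected]
  say("screening: %d/%d testable features selected", length(sel_feats),
      sum(screen$testable, na.rm = TRUE))

  g <- config$gmc
  load_true <- deletion_load(truth, subj_kept, pl$effect_band %||% "")
  gmc <- simulate_gmc(
    subj_kept, g$n_components, g$n_voxels,
    gmc_truth_config(diagnosis_component = g$diagnosis_component,
                     deletion_component = g$deletion_component,
                     deletion_fraction = g$deletion_fraction,
                     diag_effect = g$diag_effect, noise_sd = g$noise_sd),
    load = load_true, seed = stage_seed(seed, 4L))
  k <- if (identical(g$k, "mdl"))
    as.integer(estimate_order_mdl(gmc$X, stride = g$mdl_stride,
                                  seed = stage_seed(seed, 5L)))
    else as.integer(g$k)
  dec <- fix_signs(infomax_ica(gmc$X, k, seed = stage_seed(seed, 6L)))
  say("ICA: k = %d, variance explained %.4f", k, dec$variance_explained)
  net <- network_group_test(dec$A, subj_kept$diagnosis, subj_kept$age,
                            subj_kept$gender, subj_kept$site)

  assoc <- NULL; del_sum <- NULL; span <- NULL
  if (length(sel_feats)) {
    fm <- feats$counts[, sel_feats, drop = FALSE]
    assoc <- association_table(dec$A, fm, subj_kept$age,
                               subj_kept$gender, subj_kept$site,
                               alpha = config$assoc$alpha)
    top <- assoc[!assoc$skipped, ]
    top <- top[order(top$p), ][1, ]
    del_band <- feats$features$band[match(top$feature,
                                          feats$features$feature)]
    load_called <- deletion_load(
      data.frame(subject_id = calls$subject_id, cn = calls$copy_number,
                 band = band_at(cyto, calls$chrom,
                                (calls$start + calls$end) / 2)),
      subj_kept, del_band)
    del_sum <- deletion_group_anova(dec$A[, top$component], load_called)
    span <- region_span(calls[band_at(cyto, calls$chrom,
                                      (calls$start + calls$end) / 2) ==
                                del_band, , drop = FALSE])
  }
  truth_kept <- truth[truth$subject_id %in% excl$retained, , drop = FALSE]
  metrics <- evaluate_against_truth(calls, truth_kept, markers,
                                    decomposition = dec,
                                    gmc_truth = gmc$truth)
  structure(list(config = config, subjects = subjects, truth = truth,
                 qc = qc, log = log_counts, calls = calls,
                 regions = reg$regions, burden = burden,
                 burden_tests = burden_tests, features = feats,
                 screen = screen, decomposition = dec,
                 network_tests = net, assoc = assoc,
                 deletion_summary = del_sum, span = span,
                 metrics = metrics),
            class = "cytocnv_report")
}

#' Evaluate calls and decomposition against planted ground truth
#'
#' Call-level sensitivity and precision at 50% reciprocal (bp) overlap
#' within subject and chromosome; spatial-component matching correlations
#' between recovered and planted source maps.
#'
#' @param calls final call table.
#' @param truth `cnv_truth` table.
#' @param markers marker map (used to count markers spanned by truth
#'   events).
#' @param min_truth_markers only truth events spanning at least this many
#'   markers count toward sensitivity.
#' @param decomposition,gmc_truth optional ICA outputs and GMC truth.
#' @return list: `sensitivity`, `precision` (`NA` when there are no
#'   calls), `n_truth_evaluable`, `false_calls_per_sample`,
#'   `component_match` (per planted source: best |r| and matched index).
#' @export
evaluate_against_truth <- function(calls, truth, markers,
                                   min_truth_markers = 10L,
                                   decomposition = NULL,
                                   gmc_truth = NULL) {
  n_mk <- vapply(seq_len(nrow(truth)), function(i) {
    sum(markers$chrom == truth$chrom[i] & markers$pos >= truth$start[i] &
          markers$pos <= truth$end[i])
  }, numeric(1))
  ev <- truth[n_mk >= min_truth_markers, , drop = FALSE]
  match_one <- function(t_row, calls) {
    cand <- calls[calls$subject_id == t_row$subject_id &
                    calls$chrom == t_row$chrom, , drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    ov <- pmin(cand$end, t_row$end) - pmax(cand$start, t_row$start) + 1
    lt <- t_row$end - t_row$start + 1
    lc <- cand$end - cand$start + 1
    any(ov / lt >= 0.5 & ov / lc >= 0.5)
  }
  sens <- if (nrow(ev)) mean(vapply(seq_len(nrow(ev)), function(i)
    match_one(ev[i, ], calls), logical(1))) else NA_real_
  matched_call <- if (nrow(calls)) vapply(seq_len(nrow(calls)), function(i) {
    cand <- truth[truth$subject_id == calls$subject_id[i] &
                    truth$chrom == calls$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    ov <- pmin(cand$end, calls$end[i]) - pmax(cand$start, calls$start[i]) + 1
    lt <- cand$end - cand$start + 1
    lc <- calls$end[i] - calls$start[i] + 1
    any(ov / lt >= 0.5 & ov / lc >= 0.5)
  }, logical(1)) else logical(0)
  precision <- if (nrow(calls)) mean(matched_call) else NA_real_
  fp_per_sample <- if (nrow(calls))
    sum(!matched_call) / length(unique(calls$subject_id)) else 0
  comp <- NULL
  if (!is.null(decomposition) && !is.null(gmc_truth)) {
    C <- abs(cor(t(decomposition$S), t(gmc_truth$S_true)))
    comp <- data.frame(truth_component = seq_len(ncol(C)),
                       matched = apply(C, 2, which.max),
                       r = apply(C, 2, max))
  }
  list(sensitivity = sens, precision = precision,
       n_truth_evaluable = nrow(ev),
       false_calls_per_sample = fp_per_sample,
       component_match = comp)
}

#' @export
print.cytocnv_report <- function(x, ...) {
  cat("cytocnv pipeline report\n")
  cat(sprintf("  subjects: %d (QC pass %d) | planted events: %d\n",
              nrow(x$subjects), sum(x$qc), nrow(x$truth)))
  cat(sprintf("  final calls: %d in %d regions\n", nrow(x$calls),
              nrow(x$regions)))
  cat(sprintf("  screening: %d features selected\n",
              sum(x$screen$selected, na.rm = TRUE)))
  cat(sprintf("  ICA: k = %d, variance explained %.4f\n",
              x$decomposition$k, x$decomposition$variance_explained))
  if (!is.null(x$assoc)) {
    top <- x$assoc[order(x$assoc$p), ][1, ]
    cat(sprintf("  top association: component %d ~ %s (p = %.3g, dR2 = %.3f)\n",
                top$component, top$feature, top$p, top$delta_R2))
  }
  cat(sprintf("  call recovery: sensitivity %.2f, precision %s\n",
              x$metrics$sensitivity,
              format(x$metrics$precision, digits = 2)))
  invisible(x)
}
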