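#' Genome-wide CNV burden per subject
#'
#' Tallies total CNVs, total deletions, total rare CNVs and total rare
#' deletions for each subject; a call's rare status is inherited from the
#' CNV region containing it.
#'
#' @param calls call table carrying `rare` (from [define_regions()]).
#' @param subject_ids analyzed subjects (zero rows for call-free subjects).
#' @return data frame, one row per subject: `subject_id`, `total_cnvs`,
#'   `total_deletions`, `total_rare_cnvs`, `total_rare_deletions`.
#' @export
compute_burden <- function(calls, subject_ids) {
  f <- factor(calls$subject_id, levels = subject_ids)
  tab <- function(sel) as.integer(table(f[sel]))
  all_idx <- rep(TRUE, nrow(calls))
  data.frame(
    subject_id = subject_ids,
    total_cnvs = tab(all_idx),
    total_deletions = tab(calls$class == "deletion"),
    total_rare_cnvs = tab(calls$rare),
    total_rare_deletions = tab(calls$rare & calls$class == "deletion"),
    stringsAsFactors = FALSE)
}

#' Per-cytoband CNV feature matrix
#'
#' Counts each subject's CNVs, deletions and insertions within every
#' cytogenetic band. By default a call straddling a band boundary
#' increments every band it overlaps (straddlers are rare for kb-scale
#' CNVs); `rule = "midpoint"` assigns each call to the single band
#' containing its midpoint.
#'
#' @param calls call table (`subject_id`, `chrom`, `start`, `end`,
#'   `class`).
#' @param cytobands `cytoband_map`.
#' @param subject_ids analyzed subjects.
#' @param rule band-assignment rule for straddling calls.
#' @return object of class `cytoband_features`: list with `counts`
#'   (subjects x features integer matrix, feature names `<band>:<kind>` for
#'   kind in cnv/del/ins), `features` (band/kind lookup), and `testable`
#'   (bands with >= 1 CNV over all subjects).
#' @export
cytoband_features <- function(calls, cytobands, subject_ids,
                              rule = c("overlap", "midpoint")) {
  rule <- match.arg(rule)
  bands <- cytobands$bands
  kinds <- c("cnv", "del", "ins")
  feat <- as.vector(t(outer(bands$name, kinds, paste, sep = ":")))
  counts <- matrix(0L, length(subject_ids), length(feat),
                   dimnames = list(subject_ids, feat))
  for (i in seq_len(nrow(calls))) {
    if (rule == "midpoint") {
      mid <- (calls$start[i] + calls$end[i]) / 2
      hit <- bands$chrom == calls$chrom[i] & bands$start <= mid &
        mid < bands$end
    } else {
      hit <- bands$chrom == calls$chrom[i] &
        bands$start <= calls$end[i] & calls$start[i] < bands$end
    }
    kind <- if (calls$class[i] == "deletion") "del" else "ins"
    for (b in bands$name[hit]) {
      s <- calls$subject_id[i]
      counts[s, paste0(b, ":cnv")] <- counts[s, paste0(b, ":cnv")] + 1L
      counts[s, paste0(b, ":", kind)] <- counts[s, paste0(b, ":", kind)] + 1L
    }
  }
  band_tot <- vapply(bands$name,
                     function(b) sum(counts[, paste0(b, ":cnv")]),
                     numeric(1))
  structure(list(counts = counts,
                 features = data.frame(
                   feature = feat,
                   band = rep(bands$name, each = 3),
                   kind = rep(kinds, nrow(bands)),
                   stringsAsFactors = FALSE),
                 testable = setNames(band_tot >= 1, bands$name)),
            class = "cytoband_features")
}

#' Pooled-variance two-sample t-test
#'
#' Student's pooled-variance t (the plain "two-sample t-test"; Welch
#' available via `var_equal = FALSE`), with the sign convention that a
#' positive t means a higher mean in cases.
#'
#' @param x numeric feature vector.
#' @param group factor/character with levels case/control.
#' @param var_equal pooled (TRUE) or Welch (FALSE) variance.
#' @return named vector `c(t =, p =, df =)`; a zero-variance feature with
#'   equal means gives `t = 0, p = 1`.
#' @export
two_sample_t <- function(x, group, var_equal = TRUE) {
  g1 <- x[group == "case"]; g2 <- x[group == "control"]
  n1 <- length(g1); n2 <- length(g2)
  d <- mean(g1) - mean(g2)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- var(g1) / n1; v2 <- var(g2) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
  } else t <- d / se
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  c(t = t, p = p, df = df)
}

#' Partial (Type II) F-test for diagnosis with covariates
#'
#' Fits `feature ~ covariates + diagnosis` with categorical encodings and
#' reports the partial F for diagnosis given the covariates (nested-model
#' comparison), the n-way-ANOVA-style adjusted group test.
#'
#' @param x feature vector.
#' @param diagnosis case/control labels.
#' @param covariates data frame of covariates (e.g. ethnicity, tissue).
#' @return named vector `c(F =, p =)`; a constant feature gives
#'   `F = 0, p = 1`.
#' @export
ancova_f <- function(x, diagnosis, covariates) {
  if (sd(x) == 0) return(c(F = 0, p = 1))
  dat <- data.frame(.y = x, .dx = factor(diagnosis), covariates)
  full <- lm(.y ~ ., data = dat)
  red <- lm(.y ~ . - .dx, data = dat)
  a <- anova(red, full)
  Fv <- a$F[2]; p <- a$`Pr(>F)`[2]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }
  c(F = Fv, p = p)
}

#' Two-stage case/control screening of cytoband CNV features
#'
#' Stage 1: pooled two-sample t-test on all subjects at `p1`
#' (uncorrected). Stage 2: the same test restricted to White subjects at
#' `p2`, requiring the same sign of the group difference. Features -- not
#' bands -- are the unit, so one band can contribute up to three selected
#' features. Features with zero variance in either diagnosis group are
#' reported as untestable and skipped, not errored.
#'
#' @param features `cytoband_features` object (or a counts matrix).
#' @param diagnosis case/control labels, one per subject row.
#' @param white_mask logical; TRUE for White subjects.
#' @param p1,p2 stage thresholds.
#' @param var_equal pooled (default) vs Welch t.
#' @return data frame per feature: `feature`, `band`, `kind`, `t`, `p`,
#'   `t_white`, `p_white`, `testable`, `selected`.
#' @export
screen_cytobands <- function(features, diagnosis, white_mask,
                             p1 = 0.01, p2 = 0.05, var_equal = TRUE) {
  counts <- if (inherits(features, "cytoband_features")) features$counts
            else features
  info <- if (inherits(features, "cytoband_features")) features$features
          else data.frame(feature = colnames(counts),
                          band = colnames(counts), kind = "cnv")
  res <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    testable <- sd(x[diagnosis == "case"]) > 0 &&
      sd(x[diagnosis == "control"]) > 0
    if (!testable)
      return(data.frame(t = NA_real_, p = NA_real_, t_white = NA_real_,
                        p_white = NA_real_, testable = FALSE,
                        selected = FALSE))
    s1 <- two_sample_t(x, diagnosis, var_equal)
    xw <- x[white_mask]; dw <- diagnosis[white_mask]
    w_ok <- sum(dw == "case") >= 2 && sum(dw == "control") >= 2 &&
      sd(xw) > 0
    s2 <- if (w_ok) two_sample_t(xw, dw, var_equal)
          else c(t = NA_real_, p = NA_real_)
    sel <- isTRUE(s1[["p"]] < p1 && w_ok && s2[["p"]] < p2 &&
                    sign(s1[["t"]]) == sign(s2[["t"]]) && s1[["t"]] != 0)
    data.frame(t = s1[["t"]], p = s1[["p"]], t_white = s2[["t"]],
               p_white = s2[["p"]], testable = TRUE, selected = sel)
  })
  cbind(info, do.call(rbind, res))
}
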