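#' Correct Log R Ratio intensities for outliers and GC waves
#'
#' Per-sample winsorization of extreme |LRR| values, removal of principal
#' components of the marker-by-sample LRR matrix whose marker loadings
#' correlate with the GC-content track (the "genomic wave" artifact), and
#' median-centering of each sample. Optionally, per-sample mean offsets are
#' regressed on sample-level covariates (tissue type, DNA quantity proxy)
#' before centering.
#'
#' Removing wave-correlated principal components rather than regressing on
#' the GC track directly lets each sample carry its own wave amplitude, so
#' saliva-like samples with an inflated wave are corrected to blood-like
#' noise levels.
#'
#' @param lrr subjects x markers matrix (>= 3 subjects).
#' @param gc_track per-marker GC fraction.
#' @param covariates optional data frame of sample-level covariates.
#' @param winsor_quantile |LRR| quantile at which values are clipped.
#' @param gc_cor_threshold |correlation| of a component's marker loadings
#'   with `gc_track` above which the component is removed.
#' @param n_pcs number of leading principal components inspected.
#' @param max_kurtosis excess-kurtosis guard: a genomic wave is dispersed
#'   along the genome (low kurtosis marker loadings), whereas a component
#'   driven by a recurrent CNV is localized and heavy-tailed; components
#'   with excess kurtosis above this bound are never removed, so shared
#'   CNV signal survives the correction.
#' @return corrected matrix, same dimensions; attribute `removed_pcs`.
#' @export
correct_lrr <- function(lrr, gc_track, covariates = NULL,
                        winsor_quantile = 0.995, gc_cor_threshold = 0.6,
                        n_pcs = 5L, max_kurtosis = 3) {
  if (nrow(lrr) < 3) stop_arg("need >= 3 subjects to correct LRR")
  if (length(gc_track) != ncol(lrr))
    stop_arg("gc_track length != marker count")
  if (all(apply(lrr, 1, sd) == 0)) stop_arg("all-constant LRR input")
  # winsorize extreme outliers per sample
  x <- t(apply(lrr, 1, function(v) {
    lim <- quantile(abs(v), winsor_quantile, names = FALSE)
    pmin(pmax(v, -lim), lim)
  }))
  # covariate offsets (tissue, DNA quantity proxies) on per-sample means
  if (!is.null(covariates) && nrow(x) > ncol(model.matrix(~ ., covariates))) {
    off <- rowMeans(x)
    fit <- lm(off ~ ., data = covariates)
    x <- x - (fitted(fit) - mean(off))
  }
  # wave components: SVD of the marker x sample matrix (uncentered, so a
  # wave shared by all samples shows up as a leading GC-correlated
  # component rather than hiding in the marker means)
  M <- t(x)
  sv <- svd(M, nu = min(n_pcs, ncol(M)), nv = min(n_pcs, ncol(M)))
  k <- min(n_pcs, length(sv$d))
  removed <- integer(0)
  for (j in seq_len(k)) {
    u <- sv$u[, j]
    kurt <- mean((u - mean(u))^4) / (sd(u)^4) - 3
    if (abs(cor(u, gc_track)) > gc_cor_threshold && kurt < max_kurtosis) {
      M <- M - sv$d[j] * u %*% t(sv$v[, j])
      removed <- c(removed, j)
    }
  }
  # residual per-sample regression on the centered GC track: the PC step
  # captures shared wave structure; this removes each sample's leftover
  # wave amplitude (a localized CNV barely loads on the smooth track)
  gcc <- gc_track - mean(gc_track)
  beta <- as.numeric(crossprod(M, gcc)) / sum(gcc^2)
  M <- M - outer(gcc, beta)
  out <- t(M)
  out <- out - apply(out, 1, median)
  dimnames(out) <- dimnames(lrr)
  attr(out, "removed_pcs") <- removed
  attr(out, "gc_beta") <- beta
  out
}

#' Sample quality control on LRR standard deviation
#'
#' A sample passes iff its LRR standard deviation is strictly below the
#' threshold (the boundary value itself fails); default 0.28.
#'
#' @param lrr subjects x markers matrix (corrected).
#' @param sd_threshold strict upper bound on per-sample SD.
#' @return named logical vector, `TRUE` = pass.
#' @export
qc_samples <- function(lrr, sd_threshold = 0.28) {
  if (sd_threshold <= 0) stop_arg("sd_threshold must be > 0")
  sds <- apply(lrr, 1, sd)
  setNames(sds < sd_threshold, rownames(lrr))
}
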