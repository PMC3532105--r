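#' Default LRR/BAF emission parameters
#'
#' Per-copy-number Log R Ratio means follow standard SNP-array intensity
#' behaviour (homozygous deletion far negative, hemizygous deletion around
#' -0.55, neutral 0, duplications moderately positive); all values are
#' configuration, not constants, because array noise models differ by
#' platform.
#'
#' @param mu named LRR means for copy numbers 0..4.
#' @param sd named LRR standard deviations for copy numbers 0..4.
#' @param baf_sd within-cluster BAF noise SD.
#' @param allele_freq B-allele population frequency used for genotype
#'   cluster weights.
#' @export
emission_params <- function(mu = c(cn0 = -3.5, cn1 = -0.55, cn2 = 0,
                                   cn3 = 0.35, cn4 = 0.65),
                            sd = c(cn0 = 0.3, cn1 = 0.25, cn2 = 0.2,
                                   cn3 = 0.25, cn4 = 0.3),
                            baf_sd = 0.03, allele_freq = 0.5) {
  list(mu = mu, sd = sd, baf_sd = baf_sd, allele_freq = allele_freq)
}

#' Simulate one subject's LRR/BAF array
#'
#' Baseline markers emit LRR ~ Normal(0, sd) plus an additive GC wave
#' `wave_amplitude * (gc - mean(gc))`; markers inside planted events shift
#' to the copy-number-specific mean. BAF is generated from the B-allele
#' count of the local copy number (clusters at 0/0.5/1 for two copies, 0/1
#' for one copy, thirds for three copies, uniform noise for copy number 0),
#' clipped to [0, 1].
#'
#' @param subject_id subject identifier.
#' @param markers `marker_map` data frame.
#' @param cnv_truth `cnv_truth` table (events for all subjects; only this
#'   subject's rows are used).
#' @param params list from [emission_params()].
#' @param wave_amplitude GC wave amplitude (LRR units per unit of centred
#'   GC fraction).
#' @param seed RNG seed.
#' @return `sample_array` list: `subject_id`, `lrr`, `baf` over the map.
#' @export
simulate_array <- function(subject_id, markers, cnv_truth = NULL,
                           params = emission_params(),
                           wave_amplitude = 0.3, seed = 1L) {
  m <- nrow(markers)
  cn <- rep(2L, m)
  if (!is.null(cnv_truth) && nrow(cnv_truth)) {
    ev <- cnv_truth[cnv_truth$subject_id == subject_id, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (!ev$chrom[i] %in% markers$chrom)
        stop_arg("truth event on %s outside marker map", ev$chrom[i])
      sel <- markers$chrom == ev$chrom[i] &
        markers$pos >= ev$start[i] & markers$pos <= ev$end[i]
      cn[sel] <- ev$cn[i]
    }
  }
  with_seed(seed, {
    state <- cn + 1L
    lrr <- rnorm(m, params$mu[state], params$sd[state]) +
      wave_amplitude * (markers$gc - mean(markers$gc))
    p <- params$allele_freq
    bcount <- rbinom(m, cn, p)
    baf <- ifelse(cn == 0, runif(m),
                  bcount / pmax(cn, 1) + rnorm(m, 0, params$baf_sd))
    baf <- pmin(pmax(baf, 0), 1)
    structure(list(subject_id = subject_id, lrr = as.numeric(lrr),
                   baf = as.numeric(baf)),
              class = "sample_array")
  })
}

#' Ground-truth configuration for the GMC mixing model
#'
#' @param diagnosis_component component index carrying the case/control
#'   effect.
#' @param deletion_component component index whose loadings shrink with
#'   deletion load.
#' @param deletion_fraction per-copy multiplicative loading reduction `f`
#'   (loadings scale as `(1 - f)^load`; `f = 0.10` yields 10%/19% graded
#'   reductions for loads 1/2).
#' @param diag_effect additive case-minus-control loading shift.
#' @param baseline_mean,baseline_sd loading baseline distribution (means
#'   kept positive).
#' @param noise_sd additive voxel noise SD.
#' @param blob_width_frac spatial blob width as a fraction of the voxel
#'   lattice.
#' @export
gmc_truth_config <- function(diagnosis_component = 1L,
                             deletion_component = 2L,
                             deletion_fraction = 0.10,
                             diag_effect = -0.5,
                             baseline_mean = 3, baseline_sd = 0.5,
                             noise_sd = 0.3, blob_width_frac = 0.15) {
  if (deletion_fraction < 0 || deletion_fraction >= 1)
    stop_arg("deletion_fraction must be in [0, 1)")
  as.list(environment())
}

#' Simulate subject-by-voxel GMC matrices from a planted mixing model
#'
#' Generates `X = A S + E`: spatial sources `S` are smooth localized
#' Gaussian blobs on a 1-D voxel lattice (pairwise |r| < 0.1 by
#' construction), and loadings `A` combine a positive baseline, an additive
#' diagnosis effect on one designated component, a per-copy multiplicative
#' reduction `(1 - f)^load` on the deletion-effect component, and small
#' age/gender/site nuisance effects.
#'
#' @param subjects cohort table.
#' @param n_components,n_voxels decomposition scale
#'   (`n_components < min(n_subjects, n_voxels)`).
#' @param config list from [gmc_truth_config()].
#' @param load per-subject deletion load (integer 0/1/2), recycled to the
#'   cohort.
#' @param seed RNG seed.
#' @return list with `X` (subjects x voxels), and `truth` (`S_true`,
#'   `A_true`, effect registry, `noise_sd`).
#' @export
simulate_gmc <- function(subjects, n_components, n_voxels,
                         config = gmc_truth_config(),
                         load = NULL, seed = 1L) {
  n <- nrow(subjects)
  if (n_components >= min(n, n_voxels))
    stop_arg("n_components must be < min(n_subjects, n_voxels)")
  if (is.null(load)) load <- rep(0L, n)
  load <- rep_len(load, n)
  with_seed(seed, {
    centers <- (seq_len(n_components) - 0.5) / n_components * n_voxels
    width <- config$blob_width_frac * n_voxels / (2 * n_components)
    v <- seq_len(n_voxels)
    S <- t(vapply(centers, function(cc) exp(-((v - cc)^2) / (2 * width^2)),
                  numeric(n_voxels)))
    if (any(apply(S, 1, sd) == 0))
      stop_arg("degenerate configuration: zero-variance component")
    cc <- cor(t(S))
    if (max(abs(cc[upper.tri(cc)])) >= 0.1)
      stop_arg("source maps not mutually uncorrelated (|r| >= 0.1); widen lattice")
    A <- matrix(rnorm(n * n_components, config$baseline_mean,
                      config$baseline_sd), n, n_components)
    A <- pmax(A, 0.5)                       # keep effect-component means positive
    case <- subjects$diagnosis == "case"
    A[case, config$diagnosis_component] <-
      A[case, config$diagnosis_component] + config$diag_effect
    A[, config$deletion_component] <-
      A[, config$deletion_component] * (1 - config$deletion_fraction)^load
    # nuisance structure: weak age/gender/site shifts on every component
    age_c <- scale(subjects$age)[, 1]
    site_eff <- rnorm(length(unique(subjects$site)), 0, 0.05)
    names(site_eff) <- unique(subjects$site)
    nuis <- 0.02 * age_c + 0.05 * (subjects$gender == "M") +
      site_eff[subjects$site]
    A <- A + nuis
    X <- A %*% S +
      matrix(rnorm(n * n_voxels, 0, config$noise_sd), n, n_voxels)
    rownames(X) <- subjects$subject_id
    truth <- list(S_true = S, A_true = A, load = load,
                  diagnosis_component = config$diagnosis_component,
                  deletion_component = config$deletion_component,
                  deletion_fraction = config$deletion_fraction,
                  noise_sd = config$noise_sd)
    list(X = X, truth = truth)
  })
}
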