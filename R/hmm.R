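#' Parameters for the five-state copy-number HMM
#'
#' States are copy numbers 0--4. LRR emissions are Normal(mu_c, sd_c); BAF
#' emissions are genotype-cluster mixtures appropriate to each copy number
#' (uniform for CN0, clusters at 0/1 for CN1, 0/0.5/1 for CN2, thirds for
#' CN3, quarters for CN4, with binomial weights at `allele_freq`), plus a
#' small uniform floor for robustness to clipped values. Transitions are
#' distance dependent: the chance of changing state between adjacent
#' markers `d` bp apart is `p_base * (1 - exp(-d / D))`, split evenly over
#' the other states.
#'
#' @param emission list from [emission_params()].
#' @param p_base asymptotic per-step state-change probability.
#' @param D transition distance scale in bp.
#' @param init initial state probabilities (CN0..CN4).
#' @param baf_weight weight on the BAF log-likelihood (0 = LRR only).
#' @param baf_floor uniform mixture floor on BAF emissions.
#' @export
hmm_params <- function(emission = emission_params(), p_base = 0.01,
                       D = 1e5,
                       init = c(0.005, 0.02, 0.95, 0.02, 0.005),
                       baf_weight = 1, baf_floor = 0.01) {
  list(emission = emission, p_base = p_base, D = D,
       init = init / sum(init), baf_weight = baf_weight,
       baf_floor = baf_floor)
}

# BAF emission log-likelihood matrix (markers x 5 states)
baf_loglik <- function(baf, params) {
  p <- params$emission$allele_freq
  sdv <- params$emission$baf_sd
  clusters <- list(NULL,                       # CN0: uniform
                   c(0, 1),
                   c(0, 0.5, 1),
                   c(0, 1 / 3, 2 / 3, 1),
                   c(0, 0.25, 0.5, 0.75, 1))
  m <- length(baf)
  out <- matrix(0, m, 5)
  for (s in 2:5) {
    cn <- s - 1L
    w <- dbinom(0:cn, cn, p)
    dens <- rep(0, m)
    for (g in seq_along(clusters[[s]]))
      dens <- dens + w[g] * dnorm(baf, clusters[[s]][g], sdv)
    out[, s] <- log((1 - params$baf_floor) * dens + params$baf_floor)
  }
  out[, 1] <- log(1)                           # uniform on [0,1]
  out
}

#' Hidden-Markov-model segmentation of an LRR/BAF track
#'
#' Viterbi decoding of the joint LRR (+ optional BAF) emission sequence
#' under the five-state copy-number HMM of [hmm_params()]; consecutive
#' same-state runs are collapsed into segments. Neutral (CN2) segments are
#' retained in the output with `state = 2` so the consensus stage can
#' exclude them explicitly.
#'
#' @param lrr,baf numeric vectors over one chromosome (`baf = NULL` for
#'   LRR-only decoding).
#' @param positions strictly increasing bp positions.
#' @param params list from [hmm_params()].
#' @return data frame of segments: `first`, `last`, `start`, `end`,
#'   `mean_lrr`, `n_markers`, `source = "HMM"`, `state` (copy number 0--4);
#'   attribute `logprob` carries the Viterbi path log-probability.
#' @export
hmm_segment <- function(lrr, baf = NULL, positions, params = hmm_params()) {
  n <- length(lrr)
  stopifnot(length(positions) == n)
  if (is.unsorted(positions, strictly = TRUE))
    stop_arg("positions must be strictly increasing")
  em <- params$emission
  logem <- vapply(1:5, function(s) dnorm(lrr, em$mu[s], em$sd[s], log = TRUE),
                  numeric(n))
  logem <- matrix(logem, nrow = n)
  if (!is.null(baf) && params$baf_weight > 0)
    logem <- logem + params$baf_weight * baf_loglik(baf, params)
  pchange <- params$p_base * (1 - exp(-diff(positions) / params$D))
  pchange <- pmin(pmax(pchange, 1e-12), 0.5)
  res <- .viterbi_decode(logem, log(params$init), pchange)
  states <- res$path - 1L                      # copy numbers 0..4
  runs <- rle(states)
  last <- cumsum(runs$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  out <- data.frame(
    first = first, last = last, start = positions[first],
    end = positions[last],
    mean_lrr = vapply(seq_along(first),
                      function(i) mean(lrr[first[i]:last[i]]), numeric(1)),
    n_markers = runs$lengths, source = "HMM", state = runs$values,
    stringsAsFactors = FALSE)
  attr(out, "logprob") <- res$logprob
  out
}
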