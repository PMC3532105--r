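#' Fuse CBS and HMM segments into candidate CNV calls
#'
#' Only non-neutral HMM segments (state != 2) and CBS segments whose mean
#' LRR exceeds a sign-appropriate magnitude gate, each spanning >= 3
#' markers, are considered. A CBS/HMM pair matches iff their marker
#' intervals overlap, or the gap between them spans strictly fewer than
#' `max_gap_markers` intervening markers. A matched pair yields one
#' candidate call: copy number from the HMM state, marker span = the
#' intersection when overlapping, else the HMM segment's span (it carries
#' the state). Unmatched segments on either side are dropped.
#'
#' @param cbs_segments,hmm_segments segment data frames for the same
#'   sample/chromosome ([cbs_segment()], [hmm_segment()]).
#' @param positions bp positions of the chromosome's markers.
#' @param max_gap_markers strict upper bound on intervening markers.
#' @param cbs_mean_threshold |mean LRR| gate marking a CBS segment
#'   non-neutral.
#' @param min_markers minimum span of each contributing segment and of the
#'   resulting call.
#' @return data frame of candidate calls: `first`, `last`, `start`, `end`,
#'   `n_markers`, `copy_number`, `class` (`deletion` if CN in {0,1},
#'   `insertion` if CN >= 3), provenance columns `cbs_first`, `cbs_last`,
#'   `hmm_first`, `hmm_last`, and `gap_matched`.
#' @export
consensus_calls <- function(cbs_segments, hmm_segments, positions,
                            max_gap_markers = 3L, cbs_mean_threshold = 0.1,
                            min_markers = 3L) {
  empty <- data.frame(first = integer(0), last = integer(0),
                      start = numeric(0), end = numeric(0),
                      n_markers = integer(0), copy_number = integer(0),
                      class = character(0), cbs_first = integer(0),
                      cbs_last = integer(0), hmm_first = integer(0),
                      hmm_last = integer(0), gap_matched = logical(0),
                      stringsAsFactors = FALSE)
  hm <- hmm_segments[hmm_segments$state != 2L &
                       hmm_segments$n_markers >= min_markers, , drop = FALSE]
  if (!nrow(hm)) return(empty)
  cb <- cbs_segments[abs(cbs_segments$mean_lrr) >= cbs_mean_threshold &
                       cbs_segments$n_markers >= min_markers, , drop = FALSE]
  if (!nrow(cb)) return(empty)
  out <- list()
  for (h in seq_len(nrow(hm))) {
    sign_h <- sign(hm$state[h] - 2L)
    ok <- sign(cb$mean_lrr) == sign_h
    if (!any(ok)) next
    cand <- cb[ok, , drop = FALSE]
    ov_lo <- pmax(cand$first, hm$first[h])
    ov_hi <- pmin(cand$last, hm$last[h])
    overlap <- ov_hi - ov_lo + 1L             # <= 0 means disjoint
    gap <- ifelse(overlap > 0L, 0L, -overlap) # intervening markers
    match <- overlap > 0L | gap < max_gap_markers
    if (!any(match)) next
    best <- which(match)[order(-overlap[match], gap[match])][1]
    if (overlap[best] > 0L) {
      first <- ov_lo[best]; last <- ov_hi[best]; gap_matched <- FALSE
    } else {
      first <- hm$first[h]; last <- hm$last[h]; gap_matched <- TRUE
    }
    if (last - first + 1L < min_markers) next
    out[[length(out) + 1L]] <- data.frame(
      first = first, last = last, start = positions[first],
      end = positions[last], n_markers = last - first + 1L,
      copy_number = hm$state[h],
      class = if (hm$state[h] < 2L) "deletion" else "insertion",
      cbs_first = cand$first[best], cbs_last = cand$last[best],
      hmm_first = hm$first[h], hmm_last = hm$last[h],
      gap_matched = gap_matched, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Signal-to-noise filter on candidate calls
#'
#' The SNR statistic is the standardized contrast between a candidate
#' segment and its flanks: `|mean(segment LRR) - mean(flank LRR)| /
#' SD(flank LRR)`, with flanks of up to `flank_markers` markers on each
#' side, truncated at chromosome ends and excluding other candidate spans.
#' The raw ratio of means is also recorded (`snr_raw`) since the statistic
#' admits both readings. Zero flank SD with a nonzero contrast gives
#' infinite SNR (kept).
#'
#' @param candidates candidate calls for one sample/chromosome.
#' @param lrr chromosome LRR vector.
#' @param flank_markers flank width per side, in markers.
#' @param snr_threshold keep iff `snr >= snr_threshold`.
#' @return candidates with `snr`, `snr_raw` columns and rows failing the
#'   check removed; attribute `n_dropped`.
#' @export
snr_filter <- function(candidates, lrr, flank_markers = 40L,
                       snr_threshold = 2.0) {
  if (!nrow(candidates)) {
    candidates$snr <- numeric(0); candidates$snr_raw <- numeric(0)
    return(candidates)
  }
  n <- length(lrr)
  in_call <- rep(FALSE, n)
  for (i in seq_len(nrow(candidates)))
    in_call[candidates$first[i]:candidates$last[i]] <- TRUE
  snr <- snr_raw <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    lo <- candidates$first[i]; hi <- candidates$last[i]
    left <- seq(max(1L, lo - flank_markers), lo - 1L)
    right <- seq(hi + 1L, min(n, hi + flank_markers))
    left <- left[left >= 1 & left < lo]
    right <- right[right <= n & right > hi]
    fl <- c(left, right)
    fl <- fl[!in_call[fl]]
    seg_mean <- mean(lrr[lo:hi])
    if (!length(fl)) { snr[i] <- Inf; snr_raw[i] <- Inf; next }
    fm <- mean(lrr[fl]); fs <- sd(lrr[fl])
    if (length(fl) < 2 || fs == 0) {
      snr[i] <- if (seg_mean == fm) 0 else Inf
    } else snr[i] <- abs(seg_mean - fm) / fs
    snr_raw[i] <- seg_mean / fm
  }
  candidates$snr <- snr
  candidates$snr_raw <- snr_raw
  keep <- snr >= snr_threshold
  out <- candidates[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Structural filters: telomere/centromere overlap and minimum size
#'
#' Drops calls whose bp-overlap fraction with any telomere or centromere
#' interval exceeds `max_tel_cen_overlap`, and calls shorter than `min_bp`
#' -- except, when `cn0_exception` is on, homozygous (copy-number 0)
#' deletions, whose deep intensity signal justifies keeping sub-500 bp
#' events (e.g. a 418 bp homozygous deletion).
#'
#' @param calls call data frame with `chrom`, `start`, `end`,
#'   `copy_number`.
#' @param cytobands `cytoband_map` providing telomere/centromere intervals.
#' @param min_bp minimum call length (`end - start + 1`).
#' @param max_tel_cen_overlap maximum tolerated overlap fraction.
#' @param cn0_exception keep sub-`min_bp` homozygous deletions.
#' @return filtered calls; attribute `n_dropped`.
#' @export
structural_filters <- function(calls, cytobands, min_bp = 500,
                               max_tel_cen_overlap = 0.5,
                               cn0_exception = TRUE) {
  if (!nrow(calls)) return(calls)
  len <- calls$end - calls$start + 1
  frac <- numeric(nrow(calls))
  sp <- cytobands$special
  for (i in seq_len(nrow(calls))) {
    s <- sp[sp$chrom == calls$chrom[i], , drop = FALSE]
    if (!nrow(s)) next
    ov <- pmax(0, pmin(calls$end[i], s$end - 1) -
                 pmax(calls$start[i], s$start) + 1)
    frac[i] <- max(ov) / len[i]
  }
  too_small <- len < min_bp &
    !(cn0_exception & calls$copy_number == 0L)
  keep <- frac <= max_tel_cen_overlap & !too_small
  out <- calls[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Exclude samples with outlying total call counts
#'
#' One-sided, single-pass rule: subjects whose total CNV call count exceeds
#' the cohort mean plus `k_sd` standard deviations are excluded.
#'
#' @param calls call table with a `subject_id` column (post-filter counts).
#' @param subject_ids all analyzed subjects (zero-call subjects included in
#'   the mean/SD).
#' @param k_sd exclusion threshold in SDs.
#' @return list with `retained`, `excluded` subject id vectors and the
#'   per-subject `counts`.
#' @export
exclude_outlier_samples <- function(calls, subject_ids, k_sd = 3) {
  cnt <- table(factor(calls$subject_id, levels = subject_ids))
  cnt <- setNames(as.numeric(cnt), subject_ids)
  lim <- mean(cnt) + k_sd * sd(cnt)
  excl <- if (is.na(lim)) character(0) else subject_ids[cnt > lim]
  list(retained = setdiff(subject_ids, excl), excluded = excl,
       counts = cnt)
}

#' Merge calls across samples into CNV regions and classify rarity
#'
#' Single-linkage merge (union-find) of calls under the relation "marker
#' intervals overlap or are separated by strictly fewer than
#' `max_gap_markers` intervening markers", per chromosome. A region's span
#' is the union of its members' spans; its frequency is the number of
#' distinct carriers over the number of analyzed subjects; regions with
#' frequency below `rare_frequency` are rare.
#'
#' @param calls combined call table (`subject_id`, `chrom`, `first`,
#'   `last`, `start`, `end`, `copy_number`, `class`).
#' @param n_subjects number of retained subjects.
#' @param max_gap_markers strict gap bound in markers.
#' @param rare_frequency rarity threshold on carrier frequency.
#' @return list with `regions` (one row per region: `region_id`, `chrom`,
#'   `start`, `end`, `first`, `last`, `n_calls`, `n_carriers`, `frequency`,
#'   `rare`) and `calls` (input augmented with `region_id` and `rare`).
#' @export
define_regions <- function(calls, n_subjects, max_gap_markers = 3L,
                           rare_frequency = 0.01) {
  if (!nrow(calls)) {
    return(list(regions = data.frame(), calls = calls))
  }
  calls$region_id <- NA_integer_
  next_id <- 0L
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    o <- idx[order(calls$first[idx])]
    parent <- seq_along(o)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(o)) for (b in seq_along(o)) {
      if (b <= a) next
      ov <- min(calls$last[o[a]], calls$last[o[b]]) -
        max(calls$first[o[a]], calls$first[o[b]]) + 1L
      gap <- if (ov > 0L) 0L else -ov
      if (ov > 0L || gap < max_gap_markers)
        parent[find(a)] <- find(b)
    }
    roots <- vapply(seq_along(o), find, integer(1))
    ids <- next_id + as.integer(factor(roots))
    calls$region_id[o] <- ids
    next_id <- max(ids)
  }
  regs <- do.call(rbind, lapply(split(calls, calls$region_id), function(g) {
    data.frame(region_id = g$region_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               first = min(g$first), last = max(g$last),
               n_calls = nrow(g),
               n_carriers = length(unique(g$subject_id)),
               stringsAsFactors = FALSE)
  }))
  regs$frequency <- regs$n_carriers / n_subjects
  regs$rare <- regs$frequency < rare_frequency
  rownames(regs) <- NULL
  calls$rare <- regs$rare[match(calls$region_id, regs$region_id)]
  list(regions = regs, calls = calls)
}
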