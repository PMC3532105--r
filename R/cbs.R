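#' Circular binary segmentation of an LRR vector
#'
#' Recursive change-point search: each segment is treated as a circle and
#' the arc boundary pair maximizing the two-sample t-like contrast between
#' the arc and its complement is located (exhaustive O(n^2) scan in C++);
#' the split is accepted iff its permutation p-value is <= `alpha`
#' (marker permutation within the segment, with early stopping once
#' significance is impossible). Accepted splits recurse on each piece;
#' finally, adjacent segments whose means differ by less than `prune_tol`
#' are merged back.
#'
#' @param lrr numeric LRR vector for one chromosome.
#' @param positions bp positions (strictly increasing), same length.
#' @param alpha permutation significance level for accepting a split.
#' @param n_perm permutations per tested split.
#' @param min_markers minimum markers per segment piece.
#' @param seed RNG seed for the permutations.
#' @param prune_tol mean-difference tolerance for merging adjacent segments.
#' @return data frame of segments: `first`, `last` (1-based marker indices,
#'   inclusive), `start`, `end` (bp), `mean_lrr`, `n_markers`, `source`;
#'   segments are disjoint, ordered and cover all markers. A vector shorter
#'   than `min_markers` yields one segment with attribute
#'   `short_input = TRUE`.
#' @export
cbs_segment <- function(lrr, positions, alpha = 0.01, n_perm = 1000L,
                        min_markers = 3L, seed = 1L, prune_tol = 0.05) {
  n <- length(lrr)
  stopifnot(length(positions) == n)
  if (is.unsorted(positions, strictly = TRUE))
    stop_arg("positions must be strictly increasing")
  make_seg <- function(first, last) data.frame(
    first = first, last = last, start = positions[first],
    end = positions[last],
    mean_lrr = vapply(seq_along(first),
                      function(i) mean(lrr[first[i]:last[i]]), numeric(1)),
    n_markers = last - first + 1L, source = "CBS",
    stringsAsFactors = FALSE)
  if (n < min_markers) {
    out <- make_seg(1L, n)
    attr(out, "short_input") <- TRUE
    return(out)
  }
  bounds <- integer(0)   # split points: last index of each left piece
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_markers) return()
    x <- lrr[lo:hi]
    if (sd(x) == 0) return()
    res <- .cbs_perm_test(x, min_markers, n_perm, alpha)
    if (!res$found || res$p > alpha) return()
    i <- res$i; j <- res$j      # arc = (i+1)..j within x
    cuts <- integer(0)
    if (i > 0) cuts <- c(cuts, lo + i - 1L)
    if (j < len) cuts <- c(cuts, lo + j - 1L)
    if (!length(cuts)) return()
    bounds <<- c(bounds, cuts)
    pieces <- sort(unique(c(lo - 1L, cuts, hi)))
    for (p in seq_len(length(pieces) - 1L))
      recurse(pieces[p] + 1L, pieces[p + 1L])
  }
  with_seed(seed, recurse(1L, n))
  cuts <- sort(unique(bounds))
  first <- c(1L, cuts + 1L); last <- c(cuts, n)
  # prune: merge neighbours with near-equal means
  repeat {
    if (length(first) == 1L) break
    means <- vapply(seq_along(first),
                    function(i) mean(lrr[first[i]:last[i]]), numeric(1))
    d <- abs(diff(means))
    if (all(d >= prune_tol)) break
    i <- which.min(d)
    last[i] <- last[i + 1L]
    first <- first[-(i + 1L)]; last <- last[-(i + 1L)]
  }
  make_seg(first, last)
}
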