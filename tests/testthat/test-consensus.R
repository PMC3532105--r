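pos1k <- (1:10000) * 1000

test_that("consensus fuses overlapping CBS and HMM segments", {
  cbs <- rbind(seg_row(1, 9, 0.01), seg_row(10, 50, -0.5),
               seg_row(51, 100, 0.0))
  hmm <- rbind(seg_row(1, 19, 0.0, "HMM", state = 2L),
               seg_row(20, 60, -0.5, "HMM", state = 1L),
               seg_row(61, 100, 0.0, "HMM", state = 2L))
  out <- consensus_calls(cbs, hmm, pos1k)
  expect_equal(nrow(out), 1)
  expect_equal(out$first, 20)                  # interval intersection
  expect_equal(out$last, 50)
  expect_equal(out$copy_number, 1)
  expect_equal(out$class, "deletion")
  expect_false(out$gap_matched)
})

test_that("'apart by less than 3 markers' is strict", {
  cbs <- seg_row(10, 20, -0.5)
  hmm3 <- seg_row(24, 30, -0.5, "HMM", state = 1L)  # gap = markers 21:23
  expect_equal(nrow(consensus_calls(cbs, hmm3, pos1k)), 0)
  hmm2 <- seg_row(23, 30, -0.5, "HMM", state = 1L)  # gap = markers 21:22
  out <- consensus_calls(cbs, hmm2, pos1k)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$first, out$last), c(23, 30))   # HMM span carries state
  expect_true(out$gap_matched)
})

test_that("consensus needs both voices and respects gates", {
  cbs <- seg_row(10, 50, -0.5)
  none <- consensus_calls(cbs,
                          seg_row(1, 100, 0, "HMM", state = 2L), pos1k)
  expect_equal(nrow(none), 0)                  # no non-neutral HMM segment
  weak_cbs <- seg_row(10, 50, -0.05)           # below the magnitude gate
  hmm <- seg_row(20, 60, -0.5, "HMM", state = 1L)
  expect_equal(nrow(consensus_calls(weak_cbs, hmm, pos1k)), 0)
  short_hmm <- seg_row(20, 21, -0.5, "HMM", state = 1L)
  expect_equal(nrow(consensus_calls(cbs, short_hmm, pos1k)), 0)
  # sign-inconsistent pair never matches
  dup_hmm <- seg_row(20, 60, 0.4, "HMM", state = 3L)
  expect_equal(nrow(consensus_calls(cbs, dup_hmm, pos1k)), 0)
})

test_that("every consensus call lies within a non-neutral HMM segment", {
  set.seed(601)
  for (rep in 1:20) {
    ncb <- sample(1:4, 1); nhm <- sample(1:4, 1)
    mk <- function(n, hmm = FALSE) {
      first <- sort(sample(1:200, n))
      last <- pmin(first + sample(3:30, n, TRUE), 220)
      df <- seg_row(first, last, runif(n, -0.8, 0.8),
                    if (hmm) "HMM" else "CBS",
                    state = if (hmm) sample(c(0:1, 3:4), n, TRUE))
      df
    }
    out <- consensus_calls(mk(ncb), hm <- mk(nhm, TRUE), pos1k)
    if (!nrow(out)) next
    for (i in seq_len(nrow(out))) {
      expect_true(any(hm$first <= out$first[i] & hm$last >= out$last[i] &
                        hm$state == out$copy_number[i]))
    }
  }
})

test_that("snr_filter computes the standardized contrast", {
  n <- 100
  lrr <- rep(0, n)
  a <- 0.2 * sqrt(39 / 40)                     # flank sd exactly 0.2
  lrr[21:40] <- rep(c(a, -a), 10)
  lrr[61:80] <- rep(c(a, -a), 10)
  lrr[41:60] <- -0.6
  cand <- data.frame(first = 41L, last = 60L, start = 41e3, end = 60e3,
                     n_markers = 20L, copy_number = 1L, class = "deletion")
  kept <- snr_filter(cand, lrr, flank_markers = 20, snr_threshold = 2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$snr, 3.0, tolerance = 1e-12)

  flat <- snr_filter(transform(cand, first = 45L, last = 56L),
                     rep(0.3, n), flank_markers = 20, snr_threshold = 2)
  expect_equal(nrow(flat), 0)                  # zero contrast -> snr 0

  lrr0 <- rep(0, n); lrr0[41:60] <- -0.6      # zero flank SD, contrast > 0
  inf <- snr_filter(cand, lrr0, flank_markers = 20, snr_threshold = 2)
  expect_equal(nrow(inf), 1)
  expect_equal(inf$snr, Inf)
})

test_that("snr_filter excludes other candidate spans from flanks", {
  set.seed(602)
  lrr <- rnorm(120, 0, 0.1)
  lrr[31:50] <- -0.6; lrr[55:70] <- -0.6       # two nearby candidates
  cand <- data.frame(first = c(31L, 55L), last = c(50L, 70L),
                     start = c(31e3, 55e3), end = c(50e3, 70e3),
                     n_markers = c(20L, 16L), copy_number = c(1L, 1L),
                     class = "deletion")
  kept <- snr_filter(cand, lrr, flank_markers = 20, snr_threshold = 2)
  expect_equal(nrow(kept), 2)                  # neighbours don't poison flanks
})

test_that("structural filters enforce size and telomere/centromere rules", {
  cyto <- manual_cytoband_map(
    data.frame(chrom = "chr1", start = 1, end = 1e6 + 1, name = "1q1.1",
               stain = "gneg"),
    data.frame(chrom = "chr1", start = 500001, end = 600001,
               type = "centromere"))
  calls <- data.frame(
    chrom = "chr1",
    start = c(1000, 2000, 700000, 499601, 400601),
    end = c(1399, 2417, 710000, 500200, 401600),
    copy_number = c(1L, 0L, 1L, 1L, 1L),
    subject_id = "s1")
  # call 4: 600 bp, 200 of them inside the centromere (33%) -> kept
  # call 5: 1000 bp fully outside -> kept
  out <- structural_filters(calls, cyto, cn0_exception = TRUE)
  expect_equal(out$start, c(2000, 700000, 499601, 400601))
  out2 <- structural_filters(calls, cyto, cn0_exception = FALSE)
  expect_false(2000 %in% out2$start)           # 418 bp CN0 dropped without flag

  # overlap fraction boundary: 60% in -> dropped, 40% in -> kept
  ov <- data.frame(chrom = "chr1",
                   start = c(599402, 599602),   # 1000-bp calls
                   end = c(600401, 600601),
                   copy_number = 1L, subject_id = "s1")
  ov$inside <- c(600, 400) / 1000
  kept <- structural_filters(ov, cyto)
  expect_equal(kept$start, 599602)
})

test_that("outlier sample exclusion is one-sided and single-pass", {
  ids <- sprintf("s%02d", 1:20)
  calls_eq <- data.frame(subject_id = rep(ids, each = 2))
  ex <- exclude_outlier_samples(calls_eq, ids)
  expect_length(ex$excluded, 0)

  calls <- data.frame(subject_id = c(rep(ids[1:19], 1), rep("s20", 15)))
  ex2 <- exclude_outlier_samples(calls, ids)
  expect_equal(ex2$excluded, "s20")
  expect_length(ex2$retained, 19)
})

test_that("define_regions merges by the gap rule with transitivity", {
  mkcall <- function(sid, first, last) data.frame(
    subject_id = sid, chrom = "chr1", first = first, last = last,
    start = first * 1000, end = last * 1000, copy_number = 1L,
    class = "deletion")
  # two calls 10 markers apart -> two regions
  r <- define_regions(rbind(mkcall("a", 10, 20), mkcall("b", 31, 40)),
                      n_subjects = 100)
  expect_equal(nrow(r$regions), 2)
  # chain: A-B overlap, B-C gap 2 -> one region
  r2 <- define_regions(rbind(mkcall("a", 10, 20), mkcall("b", 18, 30),
                             mkcall("c", 33, 40)), n_subjects = 100)
  expect_equal(nrow(r2$regions), 1)
  expect_equal(r2$regions$n_carriers, 3)
  # frequency / rarity
  r3 <- define_regions(mkcall("a", 5, 15), n_subjects = 200)
  expect_equal(r3$regions$frequency, 0.005)
  expect_true(r3$regions$rare)
})

test_that("union-find agrees with brute-force transitive closure", {
  set.seed(603)
  for (rep in 1:10) {
    n <- 10
    first <- sample(1:150, n)
    last <- first + sample(3:25, n, TRUE)
    calls <- data.frame(subject_id = sprintf("s%d", 1:n), chrom = "chr1",
                        first = first, last = last, start = first * 1e3,
                        end = last * 1e3, copy_number = 1L,
                        class = "deletion")
    got <- define_regions(calls, n_subjects = n)
    # oracle: adjacency + reachability
    adj <- matrix(FALSE, n, n)
    for (a in 1:n) for (b in 1:n) {
      ov <- min(last[a], last[b]) - max(first[a], first[b]) + 1
      adj[a, b] <- ov > 0 || -ov < 3
    }
    reach <- adj
    for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ])
    oracle_groups <- apply(reach, 1, function(r) paste(which(r),
                                                       collapse = ","))
    expect_equal(length(unique(oracle_groups)), nrow(got$regions))
    # same partition, not just the same count
    sig <- function(groups) unname(sort(vapply(groups, function(g)
      paste(sort(g), collapse = "-"), character(1))))
    got_groups <- split(seq_len(n), got$calls$region_id)
    want_groups <- split(seq_len(n), match(oracle_groups,
                                           unique(oracle_groups)))
    expect_equal(sig(got_groups), sig(want_groups))
  }
})

test_that("snr and structural filters commute on sparse candidates", {
  cyto <- manual_cytoband_map(
    data.frame(chrom = "chr1", start = 1, end = 1e7 + 1, name = "1q1.1",
               stain = "gneg"),
    data.frame(chrom = "chr1", start = 1, end = 5e3 + 1,
               type = "telomere"))
  set.seed(604)
  lrr <- rnorm(2000, 0, 0.2)
  first <- c(101L, 501L, 901L, 1301L)
  last <- first + c(30L, 3L, 25L, 12L)
  for (i in seq_along(first))
    lrr[first[i]:last[i]] <- lrr[first[i]:last[i]] - runif(1, 0.3, 0.7)
  cand <- data.frame(chrom = "chr1", first = first, last = last,
                     start = first * 5000, end = last * 5000,
                     n_markers = last - first + 1L, copy_number = 1L,
                     class = "deletion", subject_id = "s1")
  a <- structural_filters(snr_filter(cand, lrr), cyto)
  b <- snr_filter(structural_filters(cand, cyto), lrr)
  expect_equal(a$first, b$first)
  expect_equal(a$snr, b$snr)
})

test_that("deletion/insertion class is a pure function of copy number", {
  hmm <- rbind(seg_row(10, 40, -3.2, "HMM", state = 0L),
               seg_row(60, 90, -0.5, "HMM", state = 1L),
               seg_row(110, 140, 0.4, "HMM", state = 3L),
               seg_row(160, 190, 0.7, "HMM", state = 4L))
  cbs <- rbind(seg_row(10, 40, -3.2), seg_row(60, 90, -0.5),
               seg_row(110, 140, 0.4), seg_row(160, 190, 0.7))
  out <- consensus_calls(cbs, hmm, pos1k)
  expect_equal(out$class,
               ifelse(out$copy_number < 2, "deletion", "insertion"))
  expect_equal(nrow(out), 4)
})
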