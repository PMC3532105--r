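test_that("generate_marker_map builds consistent maps", {
  mm <- generate_marker_map(1, 10, 2, seed = 7)
  expect_equal(nrow(mm$markers), 20)
  expect_equal(nrow(mm$cytobands$bands), 2)
  expect_false(is.unsorted(mm$markers$pos, strictly = TRUE))

  mm2 <- generate_marker_map(2, 50, 8, seed = 1)
  expect_equal(nrow(mm2$markers), 800)
  b <- mm2$cytobands$bands
  idx <- match(paste(mm2$markers$chrom, mm2$markers$band),
               paste(b$chrom, b$name))
  expect_true(all(mm2$markers$pos >= b$start[idx] &
                    mm2$markers$pos < b$end[idx]))
  expect_true(all(mm2$markers$gc >= 0.3 & mm2$markers$gc <= 0.7))
  # bands tile each chromosome without overlap
  for (ch in unique(b$chrom)) {
    bb <- b[b$chrom == ch, ]
    expect_equal(bb$start[-1], bb$end[-nrow(bb)])
  }

  expect_identical(generate_marker_map(2, 50, 8, seed = 1), mm2)
  mm3 <- generate_marker_map(2, 50, 8, seed = 2)
  expect_false(identical(mm3$markers$pos, mm2$markers$pos))

  expect_error(generate_marker_map(0, 10, 2), "counts")
})

test_that("UCSC cytoBand round trip converts coordinates", {
  mm <- tiny_map()
  path <- withr::local_tempfile(fileext = ".txt")
  write_cytoband_ucsc(mm$cytobands, path)
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw$V2[1], mm$cytobands$bands$start[1] - 1)  # 0-based start
  back <- read_cytoband_ucsc(path)
  expect_equal(back$bands$start, mm$cytobands$bands$start)
  expect_equal(back$bands$end, mm$cytobands$bands$end)
  expect_equal(back$bands$name, mm$cytobands$bands$name)
})

test_that("generate_cohort honours sizes, mixes and seeds", {
  ctrl <- generate_cohort(0, 5,
                          ethnicity_mix = c(White = 1, AA = 0, Other = 0),
                          site_mix = c(site1 = 1, site2 = 0, site3 = 0,
                                       site4 = 0),
                          seed = 4)
  expect_equal(nrow(ctrl), 5)
  expect_true(all(ctrl$diagnosis == "control"))
  expect_true(all(ctrl$ethnicity == "White"))
  expect_true(all(ctrl$site == "site1"))

  co <- generate_cohort(151, 173, seed = 1)
  expect_equal(nrow(co), 324)
  aa_case <- mean(co$ethnicity[co$diagnosis == "case"] == "AA")
  aa_ctrl <- mean(co$ethnicity[co$diagnosis == "control"] == "AA")
  expect_gt(aa_case, aa_ctrl)   # AA enriched in the patient group
  expect_false(anyNA(co))

  # replay oracle: marginals match binomial/multinomial expectations
  mix <- c(White = 0.5, AA = 0.3, Other = 0.2)
  co2 <- generate_cohort(400, 0, ethnicity_mix = mix, seed = 9)
  tab <- table(co2$ethnicity)[names(mix)]
  for (k in names(mix)) {
    bounds <- qbinom(c(0.0005, 0.9995), 400, mix[[k]])
    expect_gte(tab[[k]], bounds[1])
    expect_lte(tab[[k]], bounds[2])
  }
  expect_identical(generate_cohort(10, 10, seed = 5),
                   generate_cohort(10, 10, seed = 5))

  expect_error(generate_cohort(5, 5,
                               ethnicity_mix = c(White = 0.6, AA = 0.6,
                                                 Other = 0.1)),
               "sum to 1")
})

test_that("plant_cnvs places events per config", {
  mm <- tiny_map()
  subj <- generate_cohort(151, 173, seed = 2)

  empty <- plant_cnvs(subj, mm$cytobands,
                      planting_config(background_rate = 0, case_rate = 0,
                                      control_rate = 0,
                                      effect_band = NULL), seed = 1)
  expect_equal(nrow(empty), 0)

  cfg <- planting_config(background_rate = 0,
                         effect_band = mm$cytobands$bands$name[5],
                         case_rate = 0.08, control_rate = 0.017,
                         second_deletion_rate = 0)
  # binomial expectation oracle: E = 151*0.08 ~ 12 cases, 173*0.017 ~ 3 HC
  carriers <- replicate(10, {
    tr <- plant_cnvs(subj, mm$cytobands, cfg,
                     seed = sample.int(1e6, 1))
    dx <- subj$diagnosis[match(unique(tr$subject_id), subj$subject_id)]
    c(sum(dx == "case"), sum(dx == "control"))
  })
  expect_lt(abs(mean(carriers[1, ]) - 151 * 0.08),
            4 * sqrt(151 * 0.08 * 0.92 / 10))
  expect_lt(abs(mean(carriers[2, ]) - 173 * 0.017),
            4 * sqrt(173 * 0.017 * 0.983 / 10))

  tr <- plant_cnvs(subj, mm$cytobands, cfg, seed = 3)
  b <- mm$cytobands$bands[5, ]
  expect_true(all(tr$start >= b$start & tr$end < b$end))
  expect_true(all(tr$cn != 2))

  expect_error(plant_cnvs(subj, mm$cytobands,
                          planting_config(size_range = c(1e5, 2e6))),
               "exceeds band width")
})

test_that("simulate_array emits the stated LRR/BAF model", {
  mm <- tiny_map(mpb = 60)
  m <- nrow(mm$markers)
  a0 <- simulate_array("s1", mm$markers, NULL, wave_amplitude = 0,
                       seed = 21)
  expect_lt(abs(mean(a0$lrr)), 4 * 0.2 / sqrt(m))   # CLT bound
  expect_true(all(a0$baf >= 0 & a0$baf <= 1))

  # planted CN1 covering >= 30 markers
  pos <- mm$markers$pos
  tr <- data.frame(subject_id = "s1", chrom = "chr1",
                   start = pos[100], end = pos[140], cn = 1L,
                   band = "x")
  a1 <- simulate_array("s1", mm$markers, tr, wave_amplitude = 0,
                       seed = 22)
  expect_lt(abs(mean(a1$lrr[100:140]) + 0.55), 0.2)
  # CN1 BAF collapses to homozygous clusters
  expect_lt(mean(pmin(a1$baf[100:140], 1 - a1$baf[100:140])), 0.1)

  expect_identical(simulate_array("s1", mm$markers, tr, seed = 5),
                   simulate_array("s1", mm$markers, tr, seed = 5))
  tr_bad <- transform(tr, chrom = "chr9")
  expect_error(simulate_array("s1", mm$markers, tr_bad, seed = 1),
               "outside marker map")
})

test_that("planted-event LRR shift has the right sign almost surely", {
  mm <- tiny_map(mpb = 60, bands = 6)
  subj <- generate_cohort(10, 10, seed = 31)
  cfg <- planting_config(background_rate = 0.15, effect_band = NULL,
                         size_range = c(2e5, 4e5), del_frac = 0.5,
                         cn4_frac = 0.5)
  tr <- plant_cnvs(subj, mm$cytobands, cfg, seed = 32)
  ok <- c()
  for (i in seq_len(nrow(tr))) {
    sel <- mm$markers$pos >= tr$start[i] & mm$markers$pos <= tr$end[i]
    if (sum(sel) < 20) next
    si <- match(tr$subject_id[i], subj$subject_id)
    a <- simulate_array(tr$subject_id[i], mm$markers, tr,
                        wave_amplitude = 0, seed = 900 + si)
    shift <- mean(a$lrr[sel]) - mean(a$lrr[!sel])
    ok <- c(ok, sign(shift) == sign(tr$cn[i] - 2))
  }
  expect_gt(length(ok), 10)
  expect_gte(mean(ok), 0.95)
})

test_that("simulate_gmc implements the planted mixing model", {
  subj <- generate_cohort(10, 10, seed = 41)
  cfg0 <- gmc_truth_config(noise_sd = 0)
  g <- simulate_gmc(subj, 3, 600, cfg0, load = rep(0L, 20), seed = 42)
  expect_equal(unname(g$X), g$truth$A_true %*% g$truth$S_true)  # exact algebra
  cc <- cor(t(g$truth$S_true))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)

  # per-copy multiplicative reduction visible in A_true
  subj2 <- generate_cohort(100, 100, seed = 43)
  load <- rep(c(0L, 1L), 100)
  g2 <- simulate_gmc(subj2, 3, 600,
                     gmc_truth_config(deletion_fraction = 0.10,
                                      noise_sd = 0),
                     load = load, seed = 44)
  dc <- g2$truth$deletion_component
  ratio <- mean(g2$truth$A_true[load == 1, dc]) /
    mean(g2$truth$A_true[load == 0, dc])
  expect_lt(abs(ratio - 0.90), 0.05)

  # covariance oracle: X X'/v ~ A Cov(S)-style Gram + sigma^2 I
  subj3 <- generate_cohort(100, 100, seed = 45)
  g3 <- simulate_gmc(subj3, 4, 2000, gmc_truth_config(noise_sd = 0.3),
                     seed = 46)
  v <- ncol(g3$X)
  emp <- tcrossprod(g3$X) / v
  model <- tcrossprod(g3$truth$A_true %*% g3$truth$S_true) / v +
    diag(0.3^2, nrow(g3$X))
  expect_lt(norm(emp - model, "F") / norm(model, "F"), 0.05)

  expect_error(simulate_gmc(subj, 25, 600), "n_components")
})

test_that("signal files round-trip in the PennCNV dialect", {
  mm <- tiny_map(mpb = 10, bands = 2)
  s1 <- simulate_array("A1", mm$markers, seed = 51)
  s2 <- simulate_array("B2", mm$markers, seed = 52)
  dir <- withr::local_tempdir()
  write_signal_files(list(s1, s2), mm$markers, dir)
  hdr <- readLines(file.path(dir, "A1.txt"), n = 1)
  expect_identical(hdr,
                   "Name\tChr\tPosition\tLog R Ratio\tB Allele Freq")
  back <- read_signal_files(dir)
  expect_named(back, c("A1", "B2"))
  expect_lte(max(abs(back$A1$lrr - s1$lrr)), 5e-7)
  expect_lte(max(abs(back$B2$baf - s2$baf)), 5e-7)

  empty_dir <- withr::local_tempdir()
  write_signal_files(list(), mm$markers, empty_dir)
  expect_length(read_signal_files(empty_dir), 0)

  # corrupt one LRR cell -> parse error naming the line
  lines <- readLines(file.path(dir, "A1.txt"))
  f <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  f[4] <- "not_a_number"                      # the LRR cell
  lines[4] <- paste(f, collapse = "\t")
  writeLines(lines, file.path(dir, "A1.txt"))
  expect_error(read_signal_files(dir), "line 4")
})
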