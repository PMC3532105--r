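# Shared fixture builders. Everything is generated in code at test time.

# tiny one-chromosome map with evenly spread bands
tiny_map <- function(n_chrom = 1, mpb = 40, bands = 8, seed = 11,
                     band_bp = 1e6) {
  generate_marker_map(n_chrom, mpb, bands, seed = seed, band_bp = band_bp)
}

# hand-built cytoband map (1-based inclusive start, exclusive end)
manual_cytoband_map <- function(bands, special = NULL) {
  lens <- tapply(bands$end - 1L, bands$chrom, max)
  if (is.null(special))
    special <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), type = character(0))
  structure(list(bands = bands, special = special,
                 chrom_lengths = setNames(as.numeric(lens), names(lens))),
            class = "cytoband_map")
}

# segment row in the format cbs_segment()/hmm_segment() emit
seg_row <- function(first, last, mean_lrr, source = "CBS", state = NULL,
                    positions = NULL) {
  pos <- positions %||% ((1:10000) * 1000)
  df <- data.frame(first = first, last = last, start = pos[first],
                   end = pos[last], mean_lrr = mean_lrr,
                   n_markers = last - first + 1L, source = source,
                   stringsAsFactors = FALSE)
  if (!is.null(state)) df$state <- state
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deletion-only recovery cohort: simulate -> correct -> call -> filter,
# returning final calls plus the planted truth (shared by property and
# acceptance tests; scaled for desk runtime)
run_recovery_cohort <- function(seed, n_case = 12, n_control = 12,
                                mpb = 80, bands = 10, n_perm = 200,
                                case_rate = 0.8, control_rate = 0.2,
                                del_frac = 1, background_rate = 0.02,
                                wave_amplitude = 0.3) {
  mm <- generate_marker_map(1, mpb, bands, seed = seed)
  subjects <- generate_cohort(n_case, n_control, seed = seed + 1L)
  pl <- planting_config(background_rate = background_rate,
                        effect_band = mm$cytobands$bands$name[7],
                        case_rate = case_rate,
                        control_rate = control_rate,
                        second_deletion_rate = 0.3,
                        size_range = c(1.25e5, 3e5),
                        del_frac = del_frac, cn4_frac = 0.5)
  truth <- plant_cnvs(subjects, mm$cytobands, pl, seed = seed + 2L)
  markers <- mm$markers
  n <- nrow(subjects)
  lrr <- matrix(NA_real_, n, nrow(markers),
                dimnames = list(subjects$subject_id, NULL))
  baf <- lrr
  for (i in seq_len(n)) {
    a <- simulate_array(subjects$subject_id[i], markers, truth,
                        wave_amplitude = wave_amplitude,
                        seed = seed * 1000L + i)
    lrr[i, ] <- a$lrr
    baf[i, ] <- a$baf
  }
  corrected <- correct_lrr(lrr, markers$gc)
  qc <- qc_samples(corrected)
  caller <- default_run_config()$caller
  caller$n_perm <- n_perm
  calls <- list()
  for (sid in subjects$subject_id[qc]) {
    cc <- call_chromosome(corrected[sid, ], baf[sid, ], markers$pos,
                          caller, seed = seed * 7L + match(sid, subjects$subject_id))
    if (nrow(cc)) {
      cc$subject_id <- sid
      cc$chrom <- "chr1"
      calls[[length(calls) + 1L]] <- cc
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(subject_id = character(0), chrom = character(0),
               first = integer(0), last = integer(0), start = numeric(0),
               end = numeric(0), n_markers = integer(0),
               copy_number = integer(0), class = character(0))
  calls <- structural_filters(calls, mm$cytobands)
  list(markers = markers, cytobands = mm$cytobands, subjects = subjects,
       truth = truth, calls = calls, effect_band = pl$effect_band)
}
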