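#' Generate a synthetic case/control cohort table
#'
#' Draws a subject covariate table shaped like a multi-site schizophrenia
#' imaging-genetics cohort: diagnosis, age (group-specific normal), gender,
#' scan site (4 levels), ethnicity (White / AA / Other) and DNA tissue
#' source (blood / saliva). Defaults mirror the demographic structure of a
#' 151-case / 173-control cohort in which African-American subjects are
#' enriched in the patient group; every mix is configurable per group.
#'
#' @param n_case,n_control group sizes (>= 0).
#' @param ethnicity_mix named probability vector over
#'   `c("White","AA","Other")`, or a list with `case` and `control` entries.
#' @param site_mix probability vector over the 4 sites (or `case`/`control`
#'   list).
#' @param seed RNG seed.
#' @param age_mean,age_sd named (`case`, `control`) age distribution
#'   parameters in years.
#' @param male_prob named per-group probability of male gender.
#' @param saliva_prob per-group probability that DNA came from saliva.
#' @return data frame with `subject_id`, `diagnosis`, `age`, `gender`,
#'   `site`, `ethnicity`, `tissue`; no missing values.
#' @export
generate_cohort <- function(n_case, n_control,
                            ethnicity_mix = list(
                              case = c(White = 0.786, AA = 0.136, Other = 0.078),
                              control = c(White = 0.882, AA = 0.050, Other = 0.068)),
                            site_mix = c(site1 = 0.35, site2 = 0.17,
                                         site3 = 0.17, site4 = 0.31),
                            seed = 1L,
                            age_mean = c(case = 36, control = 33),
                            age_sd = c(case = 12, control = 11),
                            male_prob = c(case = 0.76, control = 0.65),
                            saliva_prob = c(case = 0.25, control = 0.25)) {
  if (n_case < 0 || n_control < 0) stop_arg("group sizes must be >= 0")
  per_group <- function(mix, grp) {
    m <- if (is.list(mix)) mix[[grp]] else mix
    check_prob_mix(m, paste0(grp, " mix"))
    m
  }
  with_seed(seed, {
    draw <- function(grp, n) {
      if (n == 0) return(NULL)
      em <- per_group(ethnicity_mix, grp)
      sm <- per_group(site_mix, grp)
      data.frame(
        subject_id = sprintf("%s%03d", ifelse(grp == "case", "SZ", "HC"),
                             seq_len(n)),
        diagnosis = grp,
        age = pmax(18, round(rnorm(n, age_mean[[grp]], age_sd[[grp]]))),
        gender = sample(c("M", "F"), n, TRUE,
                        c(male_prob[[grp]], 1 - male_prob[[grp]])),
        site = sample(names(sm) %||% paste0("site", seq_along(sm)),
                      n, TRUE, sm),
        ethnicity = sample(names(em), n, TRUE, em),
        tissue = sample(c("saliva", "blood"), n, TRUE,
                        c(saliva_prob[[grp]], 1 - saliva_prob[[grp]])),
        stringsAsFactors = FALSE)
    }
    out <- rbind(draw("case", n_case), draw("control", n_control))
    rownames(out) <- NULL
    out
  })
}

#' Default CNV planting configuration
#'
#' Event sizes default to the 418--5000 bp range of small cytoband CNVs;
#' the designated effect band receives deletions at a case-enriched rate
#' (defaults chosen so that a 151/173 cohort carries roughly 12 case and 3
#' control deletion carriers in expectation), with a configurable chance of
#' a second deletion in carriers (deletion load 2) and of a homozygous
#' (copy-number 0) event.
#'
#' @param background_rate per-subject, per-band probability of a background
#'   CNV (any copy number).
#' @param effect_band band name receiving case-enriched deletions (`NULL`
#'   for none).
#' @param case_rate,control_rate effect-band deletion carrier rates.
#' @param second_deletion_rate probability that an effect-band carrier
#'   receives a second deletion (load 2).
#' @param size_range event length range in bp.
#' @param hom_del_prob probability a planted deletion is copy number 0.
#' @param del_frac fraction of background events that are deletions.
#' @param cn4_frac fraction of insertions with copy number 4.
#' @param min_event_gap minimum bp gap between two deletions planted in the
#'   same subject's effect band, so the two events remain resolvable as
#'   separate calls (default half the maximum event size).
#' @export
planting_config <- function(background_rate = 0.02, effect_band = NULL,
                            case_rate = 0.08, control_rate = 0.017,
                            second_deletion_rate = 0.25,
                            size_range = c(418, 5000),
                            hom_del_prob = 0.05, del_frac = 0.52,
                            cn4_frac = 0.1, min_event_gap = NULL) {
  if (is.null(min_event_gap)) min_event_gap <- max(size_range) / 2
  cfg <- as.list(environment())
  stopifnot(size_range[1] <= size_range[2], size_range[1] > 0)
  cfg
}

#' Plant ground-truth CNV events in a cohort
#'
#' Places background CNVs uniformly within bands at `background_rate`, and
#' deletions in the designated effect band at diagnosis-specific rates,
#' producing the ground-truth event table used by the array simulator and
#' by call-recovery metrics.
#'
#' @param subjects cohort data frame from [generate_cohort()].
#' @param cytobands a `cytoband_map`.
#' @param config list from [planting_config()].
#' @param seed RNG seed.
#' @return `cnv_truth` data frame: `subject_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `cn`, `band`; attribute `config`.
#' @export
plant_cnvs <- function(subjects, cytobands, config = planting_config(),
                       seed = 1L) {
  rates <- c(config$background_rate, config$case_rate, config$control_rate)
  if (any(rates < 0 | rates > 1)) stop_arg("planting rates must be in [0,1]")
  bands <- cytobands$bands
  if (any(config$size_range[2] > bands$end - bands$start))
    stop_arg("event size range exceeds band width")
  draw_event <- function(subj, band_row, cn) {
    len <- round(runif(1, config$size_range[1], config$size_range[2]))
    start <- floor(runif(1, band_row$start, band_row$end - len))
    data.frame(subject_id = subj, chrom = band_row$chrom,
               start = start, end = start + len, cn = cn,
               band = band_row$name, stringsAsFactors = FALSE)
  }
  draw_cn <- function(deletion) {
    if (deletion) {
      if (runif(1) < config$hom_del_prob) 0L else 1L
    } else {
      if (runif(1) < config$cn4_frac) 4L else 3L
    }
  }
  with_seed(seed, {
    ev <- list()
    for (i in seq_len(nrow(subjects))) {
      subj <- subjects$subject_id[i]
      hit <- runif(nrow(bands)) < config$background_rate
      for (b in which(hit)) {
        ev[[length(ev) + 1L]] <-
          draw_event(subj, bands[b, ], draw_cn(runif(1) < config$del_frac))
      }
      if (!is.null(config$effect_band)) {
        rate <- if (subjects$diagnosis[i] == "case") config$case_rate
                else config$control_rate
        if (runif(1) < rate) {
          brow <- bands[bands$name == config$effect_band, ]
          if (nrow(brow) != 1) stop_arg("effect band '%s' not in map",
                                        config$effect_band)
          e1 <- draw_event(subj, brow, draw_cn(TRUE))
          ev[[length(ev) + 1L]] <- e1
          if (runif(1) < config$second_deletion_rate) {
            # keep the second event resolvable: retry until it clears the
            # first by min_event_gap (give up quietly after 20 tries)
            for (try in 1:20) {
              e2 <- draw_event(subj, brow, draw_cn(TRUE))
              if (e2$start > e1$end + config$min_event_gap ||
                  e2$end < e1$start - config$min_event_gap) {
                ev[[length(ev) + 1L]] <- e2
                break
              }
            }
          }
        }
      }
    }
    out <- if (length(ev)) do.call(rbind, ev) else
      data.frame(subject_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), cn = integer(0),
                 band = character(0), stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("cnv_truth", "data.frame")
    out
  })
}

#' Per-subject deletion load within one band
#'
#' Counts planted (or called) deletion events (copy number 0 or 1) per
#' subject inside a named band, capped at 2 — the "deletion load" used in
#' the loading-vs-load group comparisons.
#' @param events data frame with `subject_id`, `cn`, `band` columns.
#' @param subjects cohort table (defines the order of the result).
#' @param band band name.
#' @export
deletion_load <- function(events, subjects, band) {
  del <- events[events$band == band & events$cn < 2, , drop = FALSE]
  cnt <- table(factor(del$subject_id, levels = subjects$subject_id))
  pmin(as.integer(cnt), 2L)
}
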