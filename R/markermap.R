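#' Generate a scaled-down SNP-array marker map with a cytoband map
#'
#' Builds a deterministic, desk-scale stand-in for a genome-wide SNP/CNV
#' array: `n_chrom` chromosomes, each tiled by `bands_per_chrom` cytogenetic
#' bands of `band_bp` base pairs, with `markers_per_band` markers placed
#' uniformly at random (then sorted) inside each band. A smooth low-frequency
#' GC-content track in `[0.3, 0.7]` is attached per marker so that the
#' GC-wave correction stage has a real artifact to remove.
#'
#' Coordinates are 1-based with inclusive band start and exclusive band end,
#' so bands tile each chromosome without overlap. Telomere intervals
#' (`tel_bp` at each chromosome end) and a centromere interval (`cen_bp`
#' centred mid-chromosome) are carried on the cytoband map for the
#' structural call filters.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param markers_per_band markers placed in each band (>= 1).
#' @param bands_per_chrom cytogenetic bands per chromosome (>= 1).
#' @param seed RNG seed; the map is a pure function of the arguments.
#' @param band_bp band width in bp.
#' @param tel_bp,cen_bp telomere / centromere interval sizes in bp.
#' @return list with `markers` (a `marker_map` data frame: `marker_id`,
#'   `chrom`, `pos`, `gc`, `band`) and `cytobands` (a `cytoband_map`).
#' @export
generate_marker_map <- function(n_chrom, markers_per_band, bands_per_chrom,
                                seed = 1L, band_bp = 1e6,
                                tel_bp = 5e4, cen_bp = 1e5) {
  if (n_chrom < 1 || markers_per_band < 1 || bands_per_chrom < 1)
    stop_arg("all counts must be >= 1")
  with_seed(seed, {
    bands <- list(); specials <- list(); markers <- list()
    chrom_len <- bands_per_chrom * band_bp
    for (c in seq_len(n_chrom)) {
      chrom <- paste0("chr", c)
      start <- (seq_len(bands_per_chrom) - 1) * band_bp + 1
      end <- start + band_bp            # exclusive
      nb_p <- floor(bands_per_chrom / 2)
      nm <- c(if (nb_p > 0) paste0(c, "p", rev(seq_len(nb_p)), ".1"),
              paste0(c, "q", seq_len(bands_per_chrom - nb_p), ".1"))
      bands[[c]] <- data.frame(
        chrom = chrom, start = start, end = end, name = nm,
        stain = rep_len(c("gneg", "gpos50"), bands_per_chrom),
        stringsAsFactors = FALSE)
      mid <- chrom_len / 2
      specials[[c]] <- data.frame(
        chrom = chrom,
        start = c(1, mid - cen_bp / 2 + 1, chrom_len - tel_bp + 1),
        end = c(tel_bp + 1, mid + cen_bp / 2 + 1, chrom_len + 1),
        type = c("telomere", "centromere", "telomere"),
        stringsAsFactors = FALSE)
      pos <- unlist(lapply(seq_len(bands_per_chrom), function(b) {
        sort(sample.int(band_bp - 1L, markers_per_band) + start[b])
      }))
      # smooth GC field: two low-frequency harmonics, range [0.3, 0.7]
      ph <- runif(2, 0, 2 * pi)
      gc <- 0.5 + 0.15 * sin(2 * pi * pos / (chrom_len / 2) + ph[1]) +
        0.05 * sin(2 * pi * pos / (chrom_len / 8) + ph[2])
      band_idx <- findInterval(pos, start)
      markers[[c]] <- data.frame(
        marker_id = sprintf("snp_%d_%d", c, seq_along(pos)),
        chrom = chrom, pos = pos, gc = gc, band = nm[band_idx],
        stringsAsFactors = FALSE)
    }
    cyto <- structure(
      list(bands = do.call(rbind, bands),
           special = do.call(rbind, specials),
           chrom_lengths = setNames(rep(chrom_len, n_chrom),
                                    paste0("chr", seq_len(n_chrom)))),
      class = "cytoband_map")
    mm <- do.call(rbind, markers)
    class(mm) <- c("marker_map", "data.frame")
    list(markers = mm, cytobands = cyto)
  })
}

#' Write / read a cytoband map in the UCSC cytoBand.txt dialect
#'
#' The on-disk format is the UCSC convention (0-based `chromStart`,
#' half-open end, band name without the chromosome label, gieStain).
#' Internal coordinates are 1-based with inclusive start and exclusive end,
#' so `chromStart = start - 1` and `chromEnd = end - 1`. On read, centromere
#' intervals are reconstructed from `acen` bands when present; telomere
#' annotation is not part of the UCSC file and is re-attached from
#' `tel_bp` if requested.
#'
#' @param cytobands a `cytoband_map`.
#' @param path file path.
#' @param tel_bp telomere size to annotate on read (0 = none).
#' @return `read_cytoband_ucsc` returns a `cytoband_map`.
#' @export
write_cytoband_ucsc <- function(cytobands, path) {
  b <- cytobands$bands
  name <- sub("^[0-9XY]+", "", b$name)
  df <- data.frame(chrom = b$chrom, chromStart = b$start - 1L,
                   chromEnd = b$end - 1L, name = name, gieStain = b$stain)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytoband_ucsc
#' @export
read_cytoband_ucsc <- function(path, tel_bp = 0) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "chromStart", "chromEnd",
                                 "name", "gieStain"),
                   stringsAsFactors = FALSE)
  chromnum <- sub("^chr", "", df$chrom)
  bands <- data.frame(chrom = df$chrom, start = df$chromStart + 1L,
                      end = df$chromEnd + 1L,
                      name = paste0(chromnum, df$name),
                      stain = df$gieStain, stringsAsFactors = FALSE)
  lens <- tapply(bands$end - 1L, bands$chrom, max)
  special <- bands[bands$stain == "acen",
                   c("chrom", "start", "end")]
  if (nrow(special)) special$type <- "centromere" else special$type <- character(0)
  if (tel_bp > 0) {
    tl <- do.call(rbind, lapply(names(lens), function(ch) data.frame(
      chrom = ch, start = c(1, lens[[ch]] - tel_bp + 1),
      end = c(tel_bp + 1, lens[[ch]] + 1), type = "telomere")))
    special <- rbind(special, tl)
  }
  structure(list(bands = bands, special = special,
                 chrom_lengths = setNames(as.numeric(lens), names(lens))),
            class = "cytoband_map")
}

# band lookup for arbitrary positions; NA when outside any band
band_at <- function(cytobands, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    b <- cytobands$bands[cytobands$bands$chrom == ch, ]
    sel <- chrom == ch
    idx <- findInterval(pos[sel], b$start)
    ok <- idx >= 1 & idx <= nrow(b) & pos[sel] < b$end[pmax(idx, 1)]
    out[sel][ok] <- b$name[idx[ok]]
  }
  out
}
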