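#' Write / read per-sample marker signal files (PennCNV signal dialect)
#'
#' One tab-separated file per sample, named `<subject_id>.txt`, with header
#' `Name  Chr  Position  Log R Ratio  B Allele Freq`; numeric columns are
#' printed with 6 decimals and round-trip to that precision.
#'
#' @param samples list of `sample_array` objects.
#' @param markers `marker_map` data frame.
#' @param dir output directory (created if missing).
#' @return `write_signal_files` returns the file paths invisibly;
#'   `read_signal_files` returns a named list of `sample_array`s.
#' @export
write_signal_files <- function(samples, markers, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(samples, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".txt"))
    df <- data.frame(Name = markers$marker_id,
                     Chr = sub("^chr", "", markers$chrom),
                     Position = markers$pos,
                     lrr = sprintf("%.6f", s$lrr),
                     baf = sprintf("%.6f", s$baf))
    names(df) <- c("Name", "Chr", "Position", "Log R Ratio", "B Allele Freq")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_signal_files
#' @export
read_signal_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  out <- lapply(files, function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
    need <- c("Name", "Chr", "Position", "Log R Ratio", "B Allele Freq")
    if (!all(need %in% names(df)))
      stop_arg("%s: missing columns %s", basename(path),
               paste(setdiff(need, names(df)), collapse = ", "))
    for (col in c("Position", "Log R Ratio", "B Allele Freq")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop_arg("%s: non-numeric '%s' value at line %d", basename(path),
                 col, bad[1] + 1L)  # +1 for the header line
      df[[col]] <- v
    }
    structure(list(subject_id = sub("\\.txt$", "", basename(path)),
                   lrr = df[["Log R Ratio"]], baf = df[["B Allele Freq"]],
                   marker_id = df$Name),
              class = "sample_array")
  })
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}

#' Write / read a dense matrix as TSV (GMC matrices, loadings, maps)
#' @param x numeric matrix (row names preserved).
#' @param path file path.
#' @export
write_matrix_tsv <- function(x, path) {
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}
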