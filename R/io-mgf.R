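#' Read peak lists from an MGF file
#'
#' Parses the MGF dialect written by [write_mgf()]: one `BEGIN IONS` /
#' `END IONS` block per fingerprint with `TITLE=<sample_id>.<replicate_id>`,
#' `PEPMASS=<base peak m/z>`, `MODE=<protein|lipid>`, `NORMALIZED=<0|1>`
#' headers followed by `<mz> <intensity>` peak lines. `PEPMASS` carries the
#' base-peak m/z: an MS1 fingerprint has no precursor ion, but MGF requires
#' the field.
#'
#' @param path Path to an MGF file.
#' @return List of [peaklist()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fingernet_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  block_i <- 0L
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!identical(line, "BEGIN IONS")) {
      abort(sprintf("Line %d: expected 'BEGIN IONS', found '%s'.", i, line),
            class = "fingernet_parse_error")
    }
    block_i <- block_i + 1L
    i <- i + 1L
    headers <- character()
    mz <- numeric()
    int <- numeric()
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (identical(line, "END IONS")) { closed <- TRUE; i <- i + 1L; break }
      if (grepl("=", line, fixed = TRUE)) {
        key <- sub("=.*$", "", line)
        headers[[key]] <- sub("^[^=]*=", "", line)
      } else if (nzchar(line)) {
        parts <- strsplit(line, "[ \t]+")[[1L]]
        vals <- suppressWarnings(as.numeric(parts))
        if (length(vals) < 2L || anyNA(vals[1:2])) {
          abort(sprintf("Line %d: non-numeric peak line '%s'.", i, line),
                class = "fingernet_parse_error")
        }
        mz <- c(mz, vals[[1L]])
        int <- c(int, vals[[2L]])
      }
      i <- i + 1L
    }
    if (!closed) {
      abort(sprintf("Block %d: 'BEGIN IONS' without matching 'END IONS'.",
                    block_i), class = "fingernet_parse_error")
    }
    hget <- function(key) if (key %in% names(headers)) headers[[key]] else NULL
    title <- hget("TITLE") %||%
      abort(sprintf("Block %d: missing TITLE.", block_i),
            class = "fingernet_parse_error")
    sample_id <- sub("\\.[^.]*$", "", title)
    replicate_id <- suppressWarnings(as.integer(sub("^.*\\.", "", title)))
    if (is.na(replicate_id)) {
      abort(sprintf("Block %d: TITLE '%s' is not '<sample_id>.<replicate_id>'.",
                    block_i, title), class = "fingernet_parse_error")
    }
    normalized <- identical(hget("NORMALIZED"), "1")
    # the 6-significant-digit serialisation perturbs the unit sum; restore
    # it exactly for fingerprints stored as normalised
    if (normalized && length(int) && sum(int) > 0) int <- int / sum(int)
    out[[block_i]] <- peaklist(
      mz, int, sample_id = sample_id, replicate_id = replicate_id,
      mode = hget("MODE") %||% "protein",
      normalized = normalized
    )
  }
  out
}

#' Write peak lists to an MGF file
#'
#' Writes the fixed MGF dialect read back by [read_mgf()]: fields in a fixed
#' order, m/z with six decimals, intensities with six significant digits,
#' LF line endings. Two calls on the same input produce byte-identical files.
#'
#' @param peaklists List of non-empty [peaklist()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(peaklists, path) {
  stopifnot(is.list(peaklists))
  if (length(peaklists) == 0L) {
    abort("No peak lists to write.", class = "fingernet_bad_param")
  }
  chunks <- purrr::map_chr(peaklists, function(pl) {
    stopifnot(inherits(pl, "peaklist"))
    if (length(pl$mz) == 0L) {
      abort(sprintf("Peak list '%s' is empty; refusing to write it.",
                    pl$sample_id), class = "fingernet_bad_peaklist")
    }
    base_peak <- pl$mz[[which.max(pl$intensity)]]
    paste(
      c("BEGIN IONS",
        sprintf("TITLE=%s.%d", pl$sample_id, pl$replicate_id),
        sprintf("PEPMASS=%.6f", base_peak),
        sprintf("MODE=%s", pl$mode),
        sprintf("NORMALIZED=%d", as.integer(pl$normalized)),
        sprintf("%.6f %.6g", pl$mz, pl$intensity),
        "END IONS"),
      collapse = "\n"
    )
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(chunks, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}
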