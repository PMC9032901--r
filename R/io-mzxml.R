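#' Read profile spectra from an mzXML file
#'
#' Reads MS1 scans from an mzXML file (the format emitted by MSConvert for
#' MALDI-ToF acquisitions) into [raw_spectrum()] objects. Peak blocks are
#' base64-encoded pairs of IEEE floats in network (big-endian) byte order,
#' at 32- or 64-bit precision, optionally zlib-compressed; all four
#' combinations are decoded.
#'
#' @param path Path to an mzXML file.
#' @param ms_level_filter Retain only scans at this MS level (default 1;
#'   the pipeline compares MS1 fingerprints, so fragmentation scans in a
#'   file are skipped).
#' @param mode `"protein"`, `"lipid"`, or `"auto"` (default), in which case
#'   the mode is inferred from the scan's m/z range.
#' @param sample_id Sample identifier for the returned spectra; defaults to
#'   the file name without its extension. Scans are numbered as replicates
#'   in file order.
#'
#' @return List of [raw_spectrum()] objects, one per retained non-empty scan.
#' @export
read_mzxml <- function(path, ms_level_filter = 1L, mode = "auto",
                       sample_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fingernet_io_error")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      abort(sprintf("Malformed mzXML in '%s' (offset near: %s)",
                    path, conditionMessage(e)),
            class = "fingernet_parse_error")
    }
  )
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, ".//scan")
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  out <- list()
  rep_i <- 0L
  for (scan in scans) {
    lvl <- xml2::xml_attr(scan, "msLevel")
    if (!is.na(lvl) && as.integer(lvl) != as.integer(ms_level_filter)) next
    peaks_node <- xml2::xml_find_first(scan, "./peaks")
    if (inherits(peaks_node, "xml_missing")) next
    n_peaks <- suppressWarnings(as.integer(xml2::xml_attr(scan, "peaksCount")))
    txt <- gsub("\\s", "", xml2::xml_text(peaks_node))
    if (identical(n_peaks, 0L) || !nzchar(txt)) {
      warn(sprintf("Skipping empty scan %s in '%s'.",
                   xml2::xml_attr(scan, "num") %||% "?", path))
      next
    }
    vals <- decode_peak_block(
      txt,
      precision = xml2::xml_attr(peaks_node, "precision"),
      compression = xml2::xml_attr(peaks_node, "compressionType"),
      byte_order = xml2::xml_attr(peaks_node, "byteOrder")
    )
    if (length(vals) %% 2L != 0L) {
      abort(sprintf("Odd number of decoded values in a peak block of '%s'.",
                    path), class = "fingernet_parse_error")
    }
    mz <- vals[seq(1L, length(vals), by = 2L)]
    int <- vals[seq(2L, length(vals), by = 2L)]
    ord <- order(mz)
    mz <- mz[ord]; int <- int[ord]
    keep <- !duplicated(mz)
    mz <- mz[keep]; int <- int[keep]
    scan_mode <- if (identical(mode, "auto")) {
      if (mz[length(mz)] <= MODE_RANGES$lipid[2L]) "lipid" else "protein"
    } else mode
    rep_i <- rep_i + 1L
    out[[rep_i]] <- raw_spectrum(mz, int, sample_id = sample_id,
                                 replicate_id = rep_i, mode = scan_mode)
  }
  out
}

# Decode one base64 peak block into a numeric vector of interleaved
# (mz, intensity) values.
decode_peak_block <- function(b64, precision = "32", compression = "none",
                              byte_order = "network") {
  raw_bytes <- jsonlite::base64_dec(b64)
  compression <- tolower(compression %||% "none")
  if (is.na(compression) || compression %in% c("", "none")) {
    # uncompressed
  } else if (compression == "zlib") {
    raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  } else {
    abort(sprintf("Unsupported mzXML compression scheme: '%s'.", compression),
          class = "fingernet_unsupported_format")
  }
  size <- switch(as.character(precision %||% "32"),
                 "32" = 4L, "64" = 8L,
                 abort(sprintf("Unsupported mzXML precision: '%s'.", precision),
                       class = "fingernet_unsupported_format"))
  endian <- if (!is.na(byte_order %||% NA) &&
                tolower(byte_order) %in% c("little")) "little" else "big"
  readBin(raw_bytes, what = "double", size = size,
          n = length(raw_bytes) %/% size, endian = endian)
}

# Inverse of decode_peak_block; used by the simulator's mzXML writer and by
# round-trip tests.
encode_peak_block <- function(values, precision = 32L, compress = FALSE) {
  raw_bytes <- writeBin(as.double(values), raw(),
                        size = if (precision == 32L) 4L else 8L,
                        endian = "big")
  if (compress) raw_bytes <- memCompress(raw_bytes, type = "gzip")
  gsub("\n", "", jsonlite::base64_enc(raw_bytes), fixed = TRUE)
}

#' Write spectra to a minimal mzXML file
#'
#' Emits a minimal, standard-conforming mzXML document (one `scan` element
#' per spectrum, base64 network-order peak blocks) that [read_mzxml()] and
#' other mzXML readers accept. Intended for exporting simulated profile
#' spectra.
#'
#' @param spectra List of [raw_spectrum()] objects.
#' @param path Output file path.
#' @param precision 32 or 64 (bits per float).
#' @param compress Logical; zlib-compress peak blocks.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(spectra, path, precision = 64L, compress = FALSE) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(...) writeChar(paste0(paste0(...), "\n"), con, eos = NULL)
  wline('<?xml version="1.0" encoding="UTF-8"?>')
  wline('<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">')
  wline(sprintf(' <msRun scanCount="%d">', length(spectra)))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    block <- encode_peak_block(as.vector(rbind(s$mz, s$intensity)),
                               precision = precision, compress = compress)
    wline(sprintf('  <scan num="%d" msLevel="1" peaksCount="%d">',
                  i, length(s$mz)))
    wline(sprintf(
      '   <peaks precision="%d" byteOrder="network" compressionType="%s">%s</peaks>',
      precision, if (compress) "zlib" else "none", block))
    wline("  </scan>")
  }
  wline(" </msRun>")
  wline("</mzXML>")
  invisible(path)
}
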