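#' Construct a raw MALDI-ToF spectrum
#'
#' A `raw_spectrum` is one continuous (profile) acquisition replicate: a
#' strictly increasing m/z axis with non-negative intensities, plus the
#' identifiers needed to track it through the pipeline.
#'
#' @param mz Numeric vector of m/z values in Da, strictly increasing.
#' @param intensity Numeric vector of non-negative abundances, same length.
#' @param sample_id Character scalar identifying the isolate deposit.
#' @param replicate_id Integer scalar, the technical replicate number.
#' @param mode `"protein"` (linear mode, m/z 2000--20000) or `"lipid"`
#'   (reflectron mode, m/z 400--2000).
#' @param check_range If `TRUE`, require every point to lie inside the
#'   mode's acquisition range. Reading functions enforce this; trimmed or
#'   otherwise derived spectra may switch it off.
#'
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, sample_id, replicate_id = 1L,
                         mode = "protein", check_range = TRUE) {
  assert_mode(mode)
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) == 0L || length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have equal, non-zero length.",
          class = "fingernet_bad_spectrum")
  }
  if (anyNA(mz) || anyNA(intensity)) {
    abort("Spectrum contains missing values.", class = "fingernet_bad_spectrum")
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    abort("`mz` must be strictly increasing.", class = "fingernet_bad_spectrum")
  }
  if (any(intensity < 0)) {
    abort("Intensities must be non-negative.", class = "fingernet_bad_spectrum")
  }
  if (isTRUE(check_range)) {
    rng <- MODE_RANGES[[mode]]
    if (mz[1L] < rng[1L] || mz[length(mz)] > rng[2L]) {
      abort(
        sprintf("%s-mode spectrum has m/z outside [%g, %g] Da.",
                mode, rng[1L], rng[2L]),
        class = "fingernet_bad_spectrum"
      )
    }
  }
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate_id = as.integer(replicate_id),
         mode = mode),
    class = "raw_spectrum"
  )
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %s.%d [%s], %d points, m/z %.1f-%.1f\n",
              x$sample_id, x$replicate_id, x$mode, length(x$mz),
              x$mz[1L], x$mz[length(x$mz)]))
  invisible(x)
}

#' @export
as_tibble.raw_spectrum <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, replicate_id = x$replicate_id,
                 mode = x$mode, mz = x$mz, intensity = x$intensity)
}

#' Construct a centroided peak list
#'
#' A `peaklist` is the fingerprint of one replicate: picked peaks (ascending
#' m/z, positive intensity), the replicate identifiers, whether intensities
#' are TIC-normalised (sum to one), and quality-control flags such as
#' `"polymer_contaminated"`.
#'
#' @param mz,intensity Peak positions (Da, ascending, unique) and positive
#'   intensities.
#' @inheritParams raw_spectrum
#' @param normalized Logical; `TRUE` when the intensities sum to 1.
#' @param flags Character vector of quality-control labels.
#'
#' @return An object of class `peaklist`.
#' @export
peaklist <- function(mz, intensity, sample_id, replicate_id = 1L,
                     mode = "protein", normalized = FALSE,
                     flags = character()) {
  assert_mode(mode)
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have equal length.",
          class = "fingernet_bad_peaklist")
  }
  if (length(mz) > 0L) {
    if (anyNA(mz) || anyNA(intensity)) {
      abort("Peak list contains missing values.", class = "fingernet_bad_peaklist")
    }
    if (is.unsorted(mz, strictly = TRUE)) {
      abort("Peak m/z values must be ascending and unique.",
            class = "fingernet_bad_peaklist")
    }
    if (any(intensity <= 0)) {
      abort("Peak intensities must be positive.", class = "fingernet_bad_peaklist")
    }
    if (isTRUE(normalized) && abs(sum(intensity) - 1) > 1e-9) {
      abort("`normalized` is TRUE but intensities do not sum to 1.",
            class = "fingernet_bad_peaklist")
    }
  }
  structure(
    list(mz = mz, intensity = intensity,
         sample_id = as.character(sample_id),
         replicate_id = as.integer(replicate_id),
         mode = mode, normalized = isTRUE(normalized),
         flags = as.character(flags)),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  fl <- if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  cat(sprintf("<peaklist> %s.%d [%s], %d peaks%s%s\n",
              x$sample_id, x$replicate_id, x$mode, length(x$mz),
              if (x$normalized) ", TIC-normalised" else "", fl))
  invisible(x)
}

#' @export
as_tibble.peaklist <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, replicate_id = x$replicate_id,
                 mode = x$mode, normalized = x$normalized,
                 mz = x$mz, intensity = x$intensity)
}

#' Collect a list of peak lists into one long tibble
#'
#' @param peaklists List of [peaklist()] objects.
#' @return A tibble with one row per peak:
#'   `sample_id, replicate_id, mode, normalized, mz, intensity`.
#' @export
peaks_tbl <- function(peaklists) {
  stopifnot(is.list(peaklists))
  purrr::map_dfr(peaklists, as_tibble.peaklist)
}

#' Node identifier of a fingerprint
#'
#' Fingerprints are identified end-to-end as `<sample_id>.<replicate_id>`;
#' these ids name network nodes and similarity-matrix rows.
#'
#' @param x A `peaklist`, `raw_spectrum`, or data frame with `sample_id`
#'   and `replicate_id` columns.
#' @return Character vector of node ids.
#' @export
node_id <- function(x) {
  if (inherits(x, c("peaklist", "raw_spectrum"))) {
    return(paste(x$sample_id, x$replicate_id, sep = "."))
  }
  if (is.data.frame(x)) {
    return(paste(x$sample_id, x$replicate_id, sep = "."))
  }
  abort("Cannot derive a node id from this object.", class = "fingernet_bad_param")
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
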