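#' Greedy one-to-one peak matching between two fingerprints
#'
#' Candidate pairs are all `(i, j)` with `|mz_a[i] - mz_b[j]| <= mz_tolerance`,
#' ranked by descending intensity product, ties by smaller m/z difference,
#' then by lower `(i, j)`. Pairs are accepted in rank order iff neither peak
#' is already matched (GNPS-style greedy assignment).
#'
#' @param a,b Non-empty [peaklist()] objects.
#' @param mz_tolerance Matching tolerance in Da (> 0).
#' @return A tibble with columns `i`, `j` (peak indices into `a` and `b`).
#' @export
match_peaks <- function(a, b, mz_tolerance) {
  stopifnot(inherits(a, "peaklist"), inherits(b, "peaklist"))
  if (!is.numeric(mz_tolerance) || mz_tolerance <= 0) {
    abort("`mz_tolerance` must be > 0.", class = "fingernet_bad_param")
  }
  if (length(a$mz) == 0L || length(b$mz) == 0L) {
    abort("Peak lists must be non-empty.", class = "fingernet_bad_peaklist")
  }
  # candidates via a window walk over the sorted m/z axes
  lo <- findInterval(a$mz - mz_tolerance, b$mz) + 1L
  hi <- findInterval(a$mz + mz_tolerance, b$mz)
  n_cand <- pmax(hi - lo + 1L, 0L)
  if (sum(n_cand) == 0L) {
    return(tibble::tibble(i = integer(), j = integer()))
  }
  i <- rep.int(seq_along(a$mz), n_cand)
  j <- unlist(lapply(seq_along(a$mz), function(k) {
    if (n_cand[k] > 0L) seq.int(lo[k], hi[k]) else integer()
  }), use.names = FALSE)
  prod <- a$intensity[i] * b$intensity[j]
  dmz <- abs(a$mz[i] - b$mz[j])
  ord <- order(-prod, dmz, i, j)
  used_a <- logical(length(a$mz))
  used_b <- logical(length(b$mz))
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    ii <- i[ord[k]]; jj <- j[ord[k]]
    if (!used_a[ii] && !used_b[jj]) {
      used_a[ii] <- TRUE
      used_b[jj] <- TRUE
      keep[k] <- TRUE
    }
  }
  sel <- ord[keep]
  tibble::tibble(i = i[sel], j = j[sel])
}

#' Cosine score between two fingerprints
#'
#' The sum over greedily matched peak pairs of the intensity products,
#' divided by the product of the Euclidean intensity norms. Symmetric,
#' bounded in \[0, 1\] for non-negative intensities, equal to 1 for a
#' fingerprint against itself, and invariant under uniform intensity
#' scaling of either list.
#'
#' @inheritParams match_peaks
#' @return Cosine score in \[0, 1\].
#' @export
cosine_score <- function(a, b, mz_tolerance) {
  m <- match_peaks(a, b, mz_tolerance)
  if (nrow(m) == 0L) return(0)
  num <- sum(a$intensity[m$i] * b$intensity[m$j])
  den <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  min(num / den, 1)
}

#' All-pairs cosine similarity matrix
#'
#' Computes the cosine score for every unordered pair of fingerprints.
#' Protein and lipid fingerprints are never compared: mixing modes is an
#' error, and the two modes get separate networks.
#'
#' @param peaklists List of >= 2 [peaklist()] objects, all the same mode.
#' @param mz_tolerance Matching tolerance in Da; defaults to 2.0 (protein)
#'   or 0.2 (lipid).
#' @return A `similarity_matrix`: list with `ids` (tibble of `sample_id`,
#'   `replicate_id` in input order) and `scores` (symmetric n x n matrix,
#'   unit diagonal, node ids as dimnames).
#' @export
similarity_matrix <- function(peaklists, mz_tolerance = NULL) {
  stopifnot(is.list(peaklists))
  if (length(peaklists) < 2L) {
    abort("Need at least two peak lists.", class = "fingernet_bad_param")
  }
  modes <- unique(purrr::map_chr(peaklists, "mode"))
  if (length(modes) != 1L) {
    abort("Mixed modes: protein and lipid fingerprints are never compared.",
          class = "fingernet_mode_mismatch")
  }
  mz_tolerance <- mz_tolerance %||% unname(MATCH_TOL[[modes]])
  n <- length(peaklists)
  ids <- tibble::tibble(
    sample_id = purrr::map_chr(peaklists, "sample_id"),
    replicate_id = purrr::map_int(peaklists, "replicate_id")
  )
  labels <- node_id(ids)
  if (anyDuplicated(labels)) {
    abort("Duplicate fingerprint ids in input.", class = "fingernet_bad_param")
  }
  scores <- diag(1, n)
  for (p in seq_len(n - 1L)) {
    for (q in seq.int(p + 1L, n)) {
      s <- cosine_score(peaklists[[p]], peaklists[[q]], mz_tolerance)
      scores[p, q] <- s
      scores[q, p] <- s
    }
  }
  dimnames(scores) <- list(labels, labels)
  structure(list(ids = ids, scores = scores, mz_tolerance = mz_tolerance,
                 mode = modes),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d %s fingerprints, tolerance %g Da\n",
              nrow(x$scores), x$mode, x$mz_tolerance))
  invisible(x)
}

#' @describeIn similarity_matrix Long-format tibble of the unordered pairs
#'   (`id_a`, `id_b`, `cosine`).
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  n <- nrow(x$scores)
  labels <- rownames(x$scores)
  pairs <- which(upper.tri(x$scores), arr.ind = TRUE)
  tibble::tibble(
    id_a = labels[pairs[, 1L]],
    id_b = labels[pairs[, 2L]],
    cosine = x$scores[pairs]
  )
}
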