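TAXONOMY_COLS <- c("sample_id", "replicate_id", "order", "genus", "species",
                   "source", "mode")

#' Read a taxonomy manifest
#'
#' The manifest is a UTF-8 TSV with the exact header
#' `sample_id  replicate_id  order  genus  species  source  mode`, one row
#' per fingerprint. `source` distinguishes `reference` fingerprints
#' (trusted labels) from `query` fingerprints to be classified; `mode` is
#' `protein` or `lipid`. Taxonomic labels correspond to independent
#' identifications (e.g. 16S/ITS sequencing) and are inputs here.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the manifest columns, `replicate_id` integer.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "fingernet_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  validate_manifest(tibble::as_tibble(df))
}

validate_manifest <- function(df) {
  missing_cols <- setdiff(TAXONOMY_COLS, names(df))
  if (length(missing_cols)) {
    abort(paste0("Manifest is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fingernet_parse_error")
  }
  df <- tibble::as_tibble(df)[TAXONOMY_COLS]
  df$replicate_id <- as.integer(df$replicate_id)
  key <- paste(df$sample_id, df$replicate_id, sep = ".")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(paste0("Duplicate fingerprint id(s) in manifest: ",
                 paste(dups, collapse = ", ")),
          class = "fingernet_parse_error")
  }
  bad_source <- setdiff(unique(df$source), c("reference", "query"))
  if (length(bad_source)) {
    abort(paste0("Invalid source value(s): ", paste(bad_source, collapse = ", ")),
          class = "fingernet_parse_error")
  }
  bad_mode <- setdiff(unique(df$mode), c("protein", "lipid"))
  if (length(bad_mode)) {
    abort(paste0("Invalid mode value(s): ", paste(bad_mode, collapse = ", ")),
          class = "fingernet_parse_error")
  }
  if (any(!nzchar(df$order)) || any(!nzchar(df$genus))) {
    abort("Empty order/genus label in manifest.", class = "fingernet_parse_error")
  }
  df
}

#' Write a taxonomy manifest
#'
#' @param manifest Tibble with the manifest columns (see [read_taxonomy()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write_tsv_lf(manifest, path)
}

# Deterministic TSV writer: tab-separated, LF endings, no quoting, UTF-8.
write_tsv_lf <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- c(
    header_lines,
    paste(names(df), collapse = "\t"),
    do.call(paste, c(lapply(df, format_tsv_col), sep = "\t"))
  )
  if (nrow(df) == 0L) body <- c(header_lines, paste(names(df), collapse = "\t"))
  writeChar(paste0(paste(body, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.double(x)) sprintf("%.6g", x) else as.character(x)
}

#' Write and read network edge tables
#'
#' Edges are stored long-format as `id_a  id_b  cosine`, one undirected
#' edge per row.
#'
#' @param edges Tibble with columns `id_a`, `id_b`, `cosine`.
#' @param path File path.
#' @param header_lines Optional `#`-prefixed metadata lines written above
#'   the header.
#' @return `path` (write) or a tibble (read).
#' @export
write_edges_tsv <- function(edges, path, header_lines = character()) {
  stopifnot(all(c("id_a", "id_b", "cosine") %in% names(edges)))
  write_tsv_lf(edges[c("id_a", "id_b", "cosine")], path, header_lines)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          fileEncoding = "UTF-8")
  tibble::tibble(id_a = as.character(df$id_a), id_b = as.character(df$id_b),
                 cosine = as.numeric(df$cosine))
}

#' Write and read embedding coordinate tables
#'
#' Coordinates are stored as `sample_id  replicate_id  x  y  cluster_id`.
#'
#' @param coords Tibble with those columns.
#' @inheritParams write_edges_tsv
#' @return `path` (write) or a tibble (read).
#' @export
write_coords_tsv <- function(coords, path, header_lines = character()) {
  cols <- c("sample_id", "replicate_id", "x", "y", "cluster_id")
  stopifnot(all(cols %in% names(coords)))
  df <- coords[cols]
  df$x <- as.double(df$x); df$y <- as.double(df$y)
  write_tsv_lf(df, path, header_lines)
}

#' @rdname write_coords_tsv
#' @export
read_coords_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "integer", "numeric",
                                         "numeric", "character"),
                          fileEncoding = "UTF-8")
  tibble::as_tibble(df)
}
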