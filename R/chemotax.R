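# Percentages are reported to one decimal, rounding halves away from zero.
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Join cluster assignment rows to their manifest records by sample_id.
join_assignment <- function(assignment, manifest) {
  stopifnot(is.data.frame(assignment),
            all(c("id", "cluster_id", "singleton") %in% names(assignment)))
  manifest <- validate_manifest(manifest)
  manifest$id <- node_id(manifest)
  joined <- dplyr::left_join(assignment, manifest, by = "id")
  if (anyNA(joined$order)) {
    missing <- joined$id[is.na(joined$order)]
    abort(paste0("Fingerprint id(s) missing from the manifest: ",
                 paste(missing, collapse = ", ")),
          class = "fingernet_bad_param")
  }
  joined
}

#' Per-cluster order composition
#'
#' For every (cluster, order) pair, counts the member fingerprints and
#' expresses the count as a percentage of the order's manifest total
#' (`pct_of_order`) and of the cluster size (`pct_of_cluster`), both to one
#' decimal, halves rounded away from zero — the convention of biotyping
#' reports such as "61 fingerprints — 49.2% of Enterobacterales".
#'
#' @param assignment Cluster assignment tibble from [cluster_components()]
#'   (columns `id`, `cluster_id`, `singleton`).
#' @param manifest Taxonomy manifest covering every assigned id (see
#'   [read_taxonomy()]).
#' @param include_singletons Count singleton clusters as clusters
#'   (default `FALSE`: composition describes true clusters, singletons are
#'   reported by the concordance summary).
#' @return Tibble `cluster_id, order, count, pct_of_order, pct_of_cluster`.
#' @export
summarize_clusters <- function(assignment, manifest,
                               include_singletons = FALSE) {
  joined <- join_assignment(assignment, manifest)
  if (!include_singletons) joined <- dplyr::filter(joined, !.data$singleton)
  order_totals <- validate_manifest(manifest) |>
    dplyr::count(.data$order, name = "order_total")
  joined |>
    dplyr::count(.data$cluster_id, .data$order, name = "count") |>
    dplyr::left_join(order_totals, by = "order") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(cluster_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pct_of_order = round_half_away(100 * .data$count / .data$order_total),
      pct_of_cluster = round_half_away(100 * .data$count / .data$cluster_total)
    ) |>
    dplyr::select("cluster_id", "order", "count", "pct_of_order",
                  "pct_of_cluster") |>
    dplyr::arrange(.data$cluster_id, dplyr::desc(.data$count), .data$order)
}

#' Query concordance summary
#'
#' Classifies every query fingerprint by where it landed in the network:
#' `isolated` if it is a singleton; otherwise the orders of the other
#' members of its cluster are tallied and the query is `matched` when the
#' plurality order equals its own (plurality ties are resolved in favour of
#' the query's order, so a new cluster formed by same-order queries counts
#' as a success) and `misassigned` otherwise. Percentages are of the query
#' total, one decimal, halves away from zero.
#'
#' @inheritParams summarize_clusters
#' @return One-row tibble: `n_queries, n_matched, n_isolated, n_misassigned,
#'   pct_matched, pct_isolated, pct_misassigned`.
#' @export
summarize_query_concordance <- function(assignment, manifest) {
  joined <- join_assignment(assignment, manifest)
  queries <- dplyr::filter(joined, .data$source == "query")
  if (nrow(queries) == 0L) {
    abort("Manifest contains no query fingerprints.",
          class = "fingernet_bad_param")
  }
  status <- purrr::map_chr(seq_len(nrow(queries)), function(k) {
    q <- queries[k, ]
    if (q$singleton) return("isolated")
    mates <- joined[joined$cluster_id == q$cluster_id & joined$id != q$id, ]
    tally <- table(mates$order)
    best <- max(tally)
    own <- q$order
    own_count <- if (own %in% names(tally)) tally[[own]] else 0L
    if (own_count >= best) "matched" else "misassigned"
  })
  n <- nrow(queries)
  counts <- c(matched = sum(status == "matched"),
              isolated = sum(status == "isolated"),
              misassigned = sum(status == "misassigned"))
  tibble::tibble(
    n_queries = n,
    n_matched = unname(counts[["matched"]]),
    n_isolated = unname(counts[["isolated"]]),
    n_misassigned = unname(counts[["misassigned"]]),
    pct_matched = round_half_away(100 * counts[["matched"]] / n),
    pct_isolated = round_half_away(100 * counts[["isolated"]] / n),
    pct_misassigned = round_half_away(100 * counts[["misassigned"]] / n)
  )
}

#' Merge taxonomy manifests
#'
#' Concatenates manifests (e.g. a reference panel and a newly acquired
#' query panel). Fingerprint ids colliding between manifests of different
#' sources are disambiguated by prefixing the sample id with its source;
#' a remaining collision with conflicting taxonomy is an error.
#'
#' @param manifests List of manifest tibbles.
#' @return The merged manifest tibble. Use [summarize_manifest()] for its
#'   fingerprint/order/genus counts.
#' @export
merge_manifests <- function(manifests) {
  stopifnot(is.list(manifests))
  manifests <- purrr::map(manifests, validate_manifest)
  manifests <- purrr::discard(manifests, ~ nrow(.x) == 0L)
  if (length(manifests) == 0L) {
    abort("Nothing to merge.", class = "fingernet_bad_param")
  }
  if (length(manifests) > 1L) {
    keysets <- purrr::map(manifests, ~ paste(.x$sample_id, .x$replicate_id,
                                             sep = "."))
    all_keys <- unlist(keysets)
    colliding <- unique(all_keys[duplicated(all_keys)])
    if (length(colliding)) {
      manifests <- purrr::map2(manifests, keysets, function(m, keys) {
        hit <- keys %in% colliding
        m$sample_id[hit] <- paste(m$source[hit], m$sample_id[hit], sep = ":")
        m
      })
    }
  }
  merged <- dplyr::bind_rows(manifests)
  key <- paste(merged$sample_id, merged$replicate_id, sep = ".")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    same <- merged[key %in% dup, ]
    distinct_tax <- dplyr::distinct(same, .data$sample_id, .data$replicate_id,
                                    .data$order, .data$genus, .data$species)
    abort(paste0(
      if (nrow(distinct_tax) > length(dup)) "Conflicting taxonomy for id(s): "
      else "Duplicate id(s) after merge: ",
      paste(dup, collapse = ", ")), class = "fingernet_parse_error")
  }
  merged
}

#' Counts summary of a manifest
#'
#' @param manifest A manifest tibble.
#' @return One-row tibble `n_fingerprints, n_orders, n_genera`.
#' @export
summarize_manifest <- function(manifest) {
  manifest <- validate_manifest(manifest)
  tibble::tibble(
    n_fingerprints = nrow(manifest),
    n_orders = dplyr::n_distinct(manifest$order),
    n_genera = dplyr::n_distinct(manifest$genus)
  )
}

#' Detect a polymer repeat series in a fingerprint
#'
#' Polyethylene-glycol contamination shows up in reflectron-mode lipid
#' fingerprints as a ladder of peaks spaced by the ethylene-oxide repeat
#' (44.026 Da) and creates artifactual clusters; this scans for the longest
#' arithmetic run of peaks at that spacing.
#'
#' @param peaks A [peaklist()].
#' @param repeat_mass Repeat spacing in Da (default 44.026, ethylene oxide).
#' @param tol Spacing tolerance in Da (default 0.05).
#' @param min_run Minimum ladder length to call contamination (default 5).
#' @return Logical flag (`TRUE` = polymer series present) with attribute
#'   `run_length`, the longest ladder found.
#' @export
detect_polymer_series <- function(peaks, repeat_mass = 44.026, tol = 0.05,
                                  min_run = 5L) {
  stopifnot(inherits(peaks, "peaklist"))
  if (repeat_mass <= 0 || tol < 0 || min_run < 2L) {
    abort("Invalid polymer-series parameters.", class = "fingernet_bad_param")
  }
  mz <- peaks$mz
  n <- length(mz)
  if (n < min_run) {
    return(structure(FALSE, run_length = min(n, 1L)))
  }
  run <- rep(1L, n)  # longest ladder ending at peak i
  for (i in seq_len(n)) {
    prev <- which(abs(mz[i] - mz - repeat_mass) <= tol)
    if (length(prev)) run[i] <- 1L + max(run[prev])
  }
  best <- max(run)
  structure(best >= min_run, run_length = best)
}

#' Flag polymer-contaminated fingerprints
#'
#' Applies [detect_polymer_series()] and adds the
#' `"polymer_contaminated"` flag to fingerprints containing a ladder.
#'
#' @inheritParams detect_polymer_series
#' @param peaklists List of [peaklist()] objects.
#' @return The list with flags updated.
#' @export
flag_polymer_series <- function(peaklists, repeat_mass = 44.026, tol = 0.05,
                                min_run = 5L) {
  purrr::map(peaklists, function(pl) {
    if (isTRUE(as.logical(detect_polymer_series(pl, repeat_mass, tol,
                                                min_run)))) {
      pl$flags <- union(pl$flags, "polymer_contaminated")
    }
    pl
  })
}
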