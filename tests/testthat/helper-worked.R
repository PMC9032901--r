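# Reference-panel and query-panel manifests mirroring the published
# composition of the open biotyping dataset used as the worked example:
# 568 reference fingerprints in 13 orders / 38 genera, and 138 query
# fingerprints in 9 of those orders / 24 genera (13 genera shared), so the
# merged panel holds 706 fingerprints, 13 orders and 49 genera. Genus
# labels are synthetic stand-ins; the per-order fingerprint and genus
# counts are the published ones.

rki_order_counts <- c(
  Actinomycetales = 12, Aeromonadales = 4, Bacillales = 169,
  Burkholderiales = 166, Campylobacterales = 4, Enterobacterales = 124,
  Lactobacillales = 4, Pseudomonadales = 12, Rhizobiales = 34,
  Rhodobacterales = 4, Rhodospirillales = 4, Thiotrichales = 24,
  Xanthomonadales = 7)

rki_genus_counts <- c(
  Actinomycetales = 2, Aeromonadales = 1, Bacillales = 6,
  Burkholderiales = 7, Campylobacterales = 1, Enterobacterales = 11,
  Lactobacillales = 1, Pseudomonadales = 2, Rhizobiales = 2,
  Rhodobacterales = 1, Rhodospirillales = 1, Thiotrichales = 1,
  Xanthomonadales = 2)

bnsb_order_counts <- c(
  Actinomycetales = 11, Bacillales = 40, Burkholderiales = 36,
  Enterobacterales = 32, Lactobacillales = 2, Pseudomonadales = 3,
  Rhizobiales = 9, Rhodospirillales = 2, Xanthomonadales = 3)

# genera per query order: (shared with reference panel, new)
bnsb_genus_split <- list(
  Actinomycetales = c(1, 1), Bacillales = c(3, 2), Burkholderiales = c(3, 2),
  Enterobacterales = c(4, 2), Lactobacillales = c(1, 0),
  Pseudomonadales = c(1, 0), Rhizobiales = c(0, 2),
  Rhodospirillales = c(0, 1), Xanthomonadales = c(0, 1))

worked_manifests <- function() {
  rki <- purrr::map_dfr(names(rki_order_counts), function(o) {
    n <- rki_order_counts[[o]]
    genera <- sprintf("%s_g%02d", o, seq_len(rki_genus_counts[[o]]))
    tibble::tibble(
      sample_id = sprintf("rki_%s_%03d", o, seq_len(n)),
      replicate_id = 1L, order = o,
      genus = rep_len(genera, n), species = "sp",
      source = "reference", mode = "protein")
  })
  bnsb <- purrr::map_dfr(names(bnsb_order_counts), function(o) {
    n <- bnsb_order_counts[[o]]
    split <- bnsb_genus_split[[o]]
    genera <- c(sprintf("%s_g%02d", o, seq_len(split[1])),
                sprintf("%s_new%02d", o, seq_len(split[2])))
    tibble::tibble(
      sample_id = sprintf("bnsb_%s_%03d", o, seq_len(n)),
      replicate_id = 1L, order = o,
      genus = rep_len(genera, n), species = "sp",
      source = "query", mode = "protein")
  })
  list(rki = rki, bnsb = bnsb)
}

# Cluster assignment realising the published query partition: of 138
# query fingerprints, 81 cluster with same-order references, 44 stay
# isolated, 13 cluster with references of another order.
worked_concordance_inputs <- function() {
  m <- worked_manifests()
  man <- merge_manifests(list(m$rki, m$bnsb))
  ids <- paste(man$sample_id, man$replicate_id, sep = ".")
  is_query <- man$source == "query"
  qid <- ids[is_query]
  q_order <- man$order[is_query]
  ref_ids_of <- function(o) ids[!is_query & man$order == o]
  asn <- tibble::tibble(id = ids, cluster_id = ids, singleton = TRUE)
  set_cluster <- function(asn, node, anchor) {
    asn$cluster_id[asn$id %in% c(node, anchor)] <- anchor
    asn$singleton[asn$id %in% c(node, anchor)] <- FALSE
    asn
  }
  # 81 matched: pair each with a same-order reference
  used <- list()
  k_matched <- 0L
  for (i in seq_along(qid)) {
    if (k_matched >= 81L) break
    refs <- setdiff(ref_ids_of(q_order[i]), unlist(used))
    asn <- set_cluster(asn, qid[i], refs[[1]])
    used <- c(used, refs[[1]])
    k_matched <- k_matched + 1L
  }
  # 13 misassigned: pair with a reference from a different order
  # Thiotrichales is reference-only here, so any of its fingerprints is a
  # different-order anchor for every query
  mis_idx <- seq.int(82L, 94L)
  for (i in mis_idx) {
    stopifnot(q_order[i] != "Thiotrichales")
    refs <- setdiff(ref_ids_of("Thiotrichales"), unlist(used))
    asn <- set_cluster(asn, qid[i], refs[[1]])
    used <- c(used, refs[[1]])
  }
  # remaining 44 queries stay singletons
  list(assignment = asn, manifest = man)
}
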