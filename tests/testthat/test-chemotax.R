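# Build a manifest + assignment pair directly; cluster labels follow the
# smallest-member-id convention of cluster_components().
manifest_row <- function(sample_id, order, source = "reference",
                         genus = NULL) {
  tibble::tibble(sample_id = sample_id, replicate_id = 1L, order = order,
                 genus = genus %||% paste0(order, "_g"),
                 species = "sp", source = source, mode = "protein")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_net <- function(nodes, edge_pairs) {
  edges <- if (length(edge_pairs)) {
    tibble::tibble(
      id_a = vapply(edge_pairs, `[`, character(1), 1),
      id_b = vapply(edge_pairs, `[`, character(1), 2),
      cosine = 0.9)
  } else tibble::tibble(id_a = character(), id_b = character(),
                        cosine = numeric())
  structure(list(nodes = nodes, edges = edges, threshold = 0.7,
                 top_k = 10L), class = "fingerprint_network")
}

test_that("connected components label clusters by smallest member and flag singletons", {
  net <- make_net(paste0("n", 1:5), list())
  asn <- cluster_components(net)
  expect_true(all(asn$singleton))
  expect_identical(asn$cluster_id, asn$id)

  tri <- make_net(c("a.1", "b.1", "c.1", "d.1"),
                  list(c("a.1", "b.1"), c("b.1", "c.1"), c("a.1", "c.1")))
  asn2 <- cluster_components(tri)
  expect_identical(unique(asn2$cluster_id[1:3]), "a.1")
  expect_true(asn2$singleton[4])
  expect_identical(dplyr::n_distinct(asn2$cluster_id), 2L)
})

test_that("components agree with a breadth-first traversal oracle on random graphs", {
  set.seed(19)
  for (trial in 1:20) {
    n <- sample(5:50, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    pairs <- unique(t(apply(
      matrix(sample(n, 2 * m, replace = TRUE), ncol = 2), 1, sort)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    net <- make_net(nodes, lapply(seq_len(nrow(pairs)), function(k) {
      nodes[pairs[k, ]]
    }))
    asn <- cluster_components(net)
    oracle <- components_oracle(nodes, net$edges)
    expect_identical(setNames(asn$cluster_id, asn$id), oracle)
  }
})

test_that("cluster composition reproduces the printed percentage arithmetic", {
  # one order of 124 fingerprints, 61 of them in one cluster -> 49.2%
  man <- manifest_row(sprintf("e%03d", 1:124), "Enterobacterales")
  ids <- paste0(man$sample_id, ".1")
  asn <- tibble::tibble(
    id = ids,
    cluster_id = c(rep(ids[1], 61), ids[62:124]),
    singleton = c(rep(FALSE, 61), rep(TRUE, 63)))
  comp <- summarize_clusters(asn, man)
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$count, 61L)
  expect_identical(comp$pct_of_order, 49.2)
  expect_identical(comp$pct_of_cluster, 100)

  # 91 of 169 Bacillales across two clusters -> 53.8% of the order
  man2 <- manifest_row(sprintf("b%03d", 1:169), "Bacillales")
  ids2 <- paste0(man2$sample_id, ".1")
  asn2 <- tibble::tibble(
    id = ids2,
    cluster_id = c(rep(ids2[1], 46), rep(ids2[47], 45), ids2[92:169]),
    singleton = c(rep(FALSE, 91), rep(TRUE, 78)))
  comp2 <- summarize_clusters(asn2, man2)
  expect_identical(sum(comp2$count), 91L)
  expect_identical(sum(comp2$pct_of_order), 53.8)

  # a cluster equal to an entire order scores 100% of it
  man3 <- manifest_row(c("x1", "x2"), "Xanthomonadales")
  asn3 <- tibble::tibble(id = paste0(man3$sample_id, ".1"),
                         cluster_id = "x1.1", singleton = FALSE)
  expect_identical(summarize_clusters(asn3, man3)$pct_of_order, 100)
})

test_that("composition percentages are invariant to relabeling and sum per cluster", {
  set.seed(29)
  man <- manifest_row(sprintf("s%02d", 1:40),
                      sample(c("A", "B", "C"), 40, replace = TRUE))
  ids <- paste0(man$sample_id, ".1")
  cl <- sample(ids[1:5], 40, replace = TRUE)
  asn <- tibble::tibble(id = ids, cluster_id = cl, singleton = FALSE)
  comp <- summarize_clusters(asn, man)
  sums <- tapply(comp$pct_of_cluster, comp$cluster_id, sum)
  expect_true(all(abs(sums - 100) <= 0.2))

  relab <- asn
  relab$cluster_id <- paste0("cluster_", match(asn$cluster_id, unique(asn$cluster_id)))
  comp2 <- summarize_clusters(relab, man)
  canon <- function(df) dplyr::arrange(df[-1], .data$order, .data$count,
                                       .data$pct_of_cluster)
  expect_equal(canon(comp2), canon(comp))
})

test_that("query concordance reproduces the 138-query worked partition", {
  # 81 queries clustered with same-order references, 44 singletons,
  # 13 clustered with other-order references
  refs <- manifest_row(sprintf("r%03d", 1:400),
                       rep(c("SameOrder", "OtherOrder"), length.out = 400))
  q_man <- manifest_row(sprintf("q%03d", 1:138), "SameOrder", source = "query")
  man <- dplyr::bind_rows(refs, q_man)
  rid <- paste0(refs$sample_id, ".1")
  qid <- paste0(q_man$sample_id, ".1")
  same_refs <- rid[refs$order == "SameOrder"]
  other_refs <- rid[refs$order == "OtherOrder"]
  asn <- dplyr::bind_rows(
    tibble::tibble(id = qid[1:81], cluster_id = same_refs[1:81],
                   singleton = FALSE),
    tibble::tibble(id = qid[82:125], cluster_id = qid[82:125],
                   singleton = TRUE),
    tibble::tibble(id = qid[126:138], cluster_id = other_refs[1:13],
                   singleton = FALSE),
    tibble::tibble(id = same_refs[1:81], cluster_id = same_refs[1:81],
                   singleton = FALSE),
    tibble::tibble(id = other_refs[1:13], cluster_id = other_refs[1:13],
                   singleton = FALSE))
  # each matched/misassigned query shares a cluster with one reference;
  # pad reference clusters with a second same-order reference so the
  # plurality is well defined
  asn <- dplyr::bind_rows(
    asn,
    tibble::tibble(id = same_refs[82:162], cluster_id = same_refs[1:81],
                   singleton = FALSE),
    tibble::tibble(id = other_refs[14:26], cluster_id = other_refs[1:13],
                   singleton = FALSE))
  leftover <- setdiff(paste0(man$sample_id, ".1"), asn$id)
  asn <- dplyr::bind_rows(
    asn, tibble::tibble(id = leftover, cluster_id = leftover,
                        singleton = TRUE))
  res <- summarize_query_concordance(asn, man)
  expect_identical(res$n_queries, 138L)
  expect_identical(res$n_matched, 81L)
  expect_identical(res$n_isolated, 44L)
  expect_identical(res$n_misassigned, 13L)
  expect_identical(res$pct_matched, 58.7)
  expect_identical(res$pct_isolated, 31.9)
  expect_identical(res$pct_misassigned, 9.4)
})

test_that("concordance edge cases: all-singleton queries and plurality ties", {
  man <- dplyr::bind_rows(
    manifest_row("r1", "A"),
    manifest_row(c("q1", "q2"), "A", source = "query"))
  asn_all_iso <- tibble::tibble(id = c("r1.1", "q1.1", "q2.1"),
                                cluster_id = c("r1.1", "q1.1", "q2.1"),
                                singleton = TRUE)
  res <- summarize_query_concordance(asn_all_iso, man)
  expect_identical(res$pct_isolated, 100)

  # a query clustered with one same-order reference is matched
  asn_pair <- tibble::tibble(id = c("r1.1", "q1.1", "q2.1"),
                             cluster_id = c("r1.1", "r1.1", "q2.1"),
                             singleton = c(FALSE, FALSE, TRUE))
  expect_identical(summarize_query_concordance(asn_pair, man)$n_matched, 1L)

  # plurality tie between own order and another resolves in the query's favour
  man2 <- dplyr::bind_rows(
    manifest_row("a1", "A"), manifest_row("b1", "B"),
    manifest_row("q1", "A", source = "query"))
  asn_tie <- tibble::tibble(id = c("a1.1", "b1.1", "q1.1"),
                            cluster_id = "a1.1",
                            singleton = FALSE)
  expect_identical(summarize_query_concordance(asn_tie, man2)$n_matched, 1L)

  # a new cluster formed only by same-order queries counts as matched
  man3 <- dplyr::bind_rows(
    manifest_row("r1", "A"),
    manifest_row(c("q1", "q2"), "A", source = "query"))
  asn_new <- tibble::tibble(id = c("r1.1", "q1.1", "q2.1"),
                            cluster_id = c("r1.1", "q1.1", "q1.1"),
                            singleton = c(TRUE, FALSE, FALSE))
  expect_identical(summarize_query_concordance(asn_new, man3)$n_matched, 2L)

  expect_error(summarize_query_concordance(asn_new, manifest_row("r1", "A")),
               class = "fingernet_bad_param")
})

test_that("concordance counts partition random query sets", {
  set.seed(37)
  for (trial in 1:10) {
    n <- sample(10:60, 1)
    man <- manifest_row(sprintf("s%02d", 1:n),
                        sample(c("A", "B"), n, replace = TRUE),
                        source = sample(c("reference", "query"), n,
                                        replace = TRUE, prob = c(0.4, 0.6)))
    if (!any(man$source == "query")) next
    ids <- paste0(man$sample_id, ".1")
    anchors <- sample(ids, 5)
    cl <- sample(anchors, n, replace = TRUE)
    sizes <- table(cl)[cl]
    asn <- tibble::tibble(id = ids,
                          cluster_id = as.vector(ifelse(sizes == 1, ids, cl)),
                          singleton = as.vector(sizes == 1))
    res <- summarize_query_concordance(asn, man)
    expect_identical(res$n_matched + res$n_isolated + res$n_misassigned,
                     res$n_queries)
  }
})

test_that("manifest merge counts fingerprints, orders and genera on the union", {
  a <- manifest_row(c("a1", "a2"), "A", genus = c("g1", "g2"))
  b <- manifest_row(c("b1", "b2", "b3"), c("A", "B", "B"),
                    genus = c("g2", "g3", "g3"))
  merged <- merge_manifests(list(a, b))
  counts <- summarize_manifest(merged)
  expect_identical(counts$n_fingerprints, 5L)
  expect_identical(counts$n_orders, 2L)
  expect_identical(counts$n_genera, 3L)

  expect_equal(merge_manifests(list(a, a[0, ])), a)

  # self-merge after id prefixing doubles counts, keeps orders
  a2 <- a; a2$sample_id <- paste0("dup_", a2$sample_id)
  doubled <- summarize_manifest(merge_manifests(list(a, a2)))
  expect_identical(doubled$n_fingerprints, 4L)
  expect_identical(doubled$n_orders, 1L)

  # colliding ids from different sources are prefixed apart
  b_query <- a; b_query$source <- "query"; b_query$order <- "A"
  m <- merge_manifests(list(a, b_query))
  expect_identical(nrow(m), 4L)
  expect_true(any(grepl("^reference:", m$sample_id)))

  # conflicting taxonomy within one source is an error
  a_conflict <- a; a_conflict$order <- "Z"
  expect_error(merge_manifests(list(a, a_conflict)),
               class = "fingernet_parse_error")
})

test_that("PEG ladders are detected and near-ladders are not", {
  ladder <- peaklist(400 + 44.026 * 0:9, rep(1, 10), "peg", 1L, "lipid")
  hit <- detect_polymer_series(ladder)
  expect_true(as.logical(hit))
  expect_identical(attr(hit, "run_length"), 10L)

  short <- peaklist(400 + 44.026 * 0:3, rep(1, 4), "peg", 1L, "lipid")
  expect_false(as.logical(detect_polymer_series(short, min_run = 5L)))

  # ladder of exactly min_run - 1 among other peaks
  mz <- sort(c(400 + 44.026 * 0:3, 700.3, 801.7, 903.9))
  near <- peaklist(mz, rep(1, length(mz)), "x", 1L, "lipid")
  expect_false(as.logical(detect_polymer_series(near, min_run = 5L)))

  flagged <- flag_polymer_series(list(ladder, short))
  expect_identical(flagged[[1]]$flags, "polymer_contaminated")
  expect_identical(flagged[[2]]$flags, character())
})

test_that("random lipid fingerprints are flagged at under 1% false-positive rate", {
  set.seed(43)
  n_draw <- 1000
  fp <- 0
  for (k in seq_len(n_draw)) {
    pl <- random_peaklist(20, 400, 2000, min_gap = 2)
    hit <- detect_polymer_series(pl)
    # brute-force longest-run check confirms every flag
    run_oracle <- function(mz, rep_m = 44.026, tol = 0.05) {
      best <- 1
      for (i in seq_along(mz)) {
        len <- 1; cur <- mz[i]
        repeat {
          nxt <- which(abs(mz - cur - rep_m) <= tol)
          if (!length(nxt)) break
          cur <- mz[nxt[1]]; len <- len + 1
        }
        best <- max(best, len)
      }
      best
    }
    expect_identical(as.logical(hit), run_oracle(pl$mz) >= 5)
    if (as.logical(hit)) fp <- fp + 1
  }
  expect_lt(fp / n_draw, 0.01)
})

test_that("dropping polymer-flagged fingerprints never adds cross-order edges", {
  cfg <- sim_config(mode = "lipid", n_orders = 3L, genera_per_order = 2L,
                    peg_prob = 0.3, seed = 57L)
  panel <- simulate_panel(cfg)
  flagged <- flag_polymer_series(panel$peaklists)
  is_flagged <- vapply(flagged, function(p)
    "polymer_contaminated" %in% p$flags, logical(1))
  expect_gt(sum(is_flagged), 0L)

  cross_order_edges <- function(pls) {
    sm <- similarity_matrix(pls)
    net <- build_network(sm, 0.3, 10L)
    ord <- panel$manifest$order[match(
      sub("\\.[0-9]+$", "", net$edges$id_a), panel$manifest$sample_id)]
    ord_b <- panel$manifest$order[match(
      sub("\\.[0-9]+$", "", net$edges$id_b), panel$manifest$sample_id)]
    sum(ord != ord_b)
  }
  with_peg <- cross_order_edges(flagged)
  without_peg <- cross_order_edges(flagged[!is_flagged])
  expect_lte(without_peg, with_peg)
})
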