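#' Build a thresholded mutual top-k similarity network
#'
#' Candidate edges are unordered pairs with cosine >= `threshold`. A
#' candidate edge is retained iff each endpoint ranks the other within its
#' `top_k` strongest candidates (ties broken by node order), the mutual
#' top-k rule of molecular networking, which prevents hub nodes. Nodes with
#' no retained edge remain in the network as isolated nodes.
#'
#' @param matrix A [similarity_matrix()].
#' @param threshold Minimum cosine for a candidate edge, in \[0, 1\].
#' @param top_k Neighbour budget per node (>= 1).
#' @return A `fingerprint_network`: list with `nodes` (character ids in
#'   input order), `edges` (tibble `id_a`, `id_b`, `cosine`), `threshold`,
#'   `top_k`.
#' @export
build_network <- function(matrix, threshold = 0.7, top_k = 10L) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (threshold < 0) {
    abort("`threshold` must be >= 0.", class = "fingernet_bad_param")
  }
  if (top_k < 1L) abort("`top_k` must be >= 1.", class = "fingernet_bad_param")
  s <- matrix$scores
  n <- nrow(s)
  labels <- rownames(s)
  # per-node candidate ranks: descending cosine, ties by node order
  rank_of <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- setdiff(which(s[i, ] >= threshold), i)
    rank_of[[i]] <- cand[order(-s[i, cand], cand)]
  }
  ia <- integer(); ib <- integer(); w <- numeric()
  for (i in seq_len(n)) {
    tki <- head(rank_of[[i]], top_k)
    for (j in tki) {
      if (j > i && i %in% head(rank_of[[j]], top_k)) {
        ia <- c(ia, i); ib <- c(ib, j); w <- c(w, s[i, j])
      }
    }
  }
  structure(
    list(nodes = labels,
         edges = tibble::tibble(id_a = labels[ia], id_b = labels[ib],
                                cosine = w),
         threshold = threshold, top_k = as.integer(top_k)),
    class = "fingerprint_network"
  )
}

#' @export
print.fingerprint_network <- function(x, ...) {
  cat(sprintf("<fingerprint_network> %d nodes, %d edges (cosine >= %g, mutual top-%d)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$top_k))
  invisible(x)
}

#' @describeIn build_network Edge tibble of the network.
#' @param x A `fingerprint_network`.
#' @param ... Unused.
#' @export
tidy.fingerprint_network <- function(x, ...) x$edges

#' Clusters as connected components of the network
#'
#' The reproducible surrogate for clusters drawn by eye on an embedding:
#' a cluster is a connected component of the thresholded mutual top-k
#' network. Each cluster is labelled by its smallest member id (first in
#' node order); degree-zero nodes are singletons.
#'
#' @param network A [build_network()] result.
#' @return A tibble with one row per node: `id`, `cluster_id` (the smallest
#'   member id of the component), `singleton`.
#' @export
cluster_components <- function(network) {
  stopifnot(inherits(network, "fingerprint_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[c("id_a", "id_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[network$nodes]
  rep_id <- vapply(
    split(network$nodes, membership)[as.character(membership)],
    function(ids) ids[[1L]],  # node order within a component is input order
    character(1)
  )
  degree <- igraph::degree(g)[network$nodes]
  tibble::tibble(id = network$nodes,
                 cluster_id = unname(rep_id),
                 singleton = unname(degree) == 0L)
}
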