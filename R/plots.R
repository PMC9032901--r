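#' Plot a t-SNE embedding
#'
#' Scatter plot of the embedded fingerprints, optionally coloured by the
#' taxonomic order from a manifest (the usual way chemotaxonomic maps are
#' read) or by cluster.
#'
#' @param object A `fingerprint_embedding`.
#' @param manifest Optional manifest tibble; points are coloured by `order`.
#' @param assignment Optional assignment tibble from [cluster_components()];
#'   used for colour when no manifest is given.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fingerprint_embedding <- function(object, manifest = NULL,
                                           assignment = NULL, ...) {
  df <- tidy(object)
  df$id <- node_id(df)
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    df$order <- manifest$order[match(df$sample_id, manifest$sample_id)]
    colour <- "order"
  } else if (!is.null(assignment)) {
    df$cluster_id <- assignment$cluster_id[match(df$id, assignment$id)]
    colour <- "cluster_id"
  } else {
    colour <- NULL
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  }
}

#' Plot a similarity network
#'
#' Draws the mutual top-k network with nodes at the embedding coordinates
#' (or, failing that, at a deterministic classical-MDS layout of
#' `1 - cosine`), edges weighted by cosine score.
#'
#' @param object A `fingerprint_network`.
#' @param embedding Optional `fingerprint_embedding` supplying the node
#'   layout.
#' @param manifest Optional manifest for colouring nodes by order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fingerprint_network <- function(object, embedding = NULL,
                                         manifest = NULL, ...) {
  if (!is.null(embedding)) {
    layout <- tidy(embedding)
    layout$id <- node_id(layout)
  } else {
    abort("Supply `embedding` to lay out the network.",
          class = "fingernet_bad_param")
  }
  nodes <- tibble::tibble(id = object$nodes)
  nodes <- dplyr::left_join(nodes, layout, by = "id")
  edges <- object$edges
  edges$x <- nodes$x[match(edges$id_a, nodes$id)]
  edges$y <- nodes$y[match(edges$id_a, nodes$id)]
  edges$xend <- nodes$x[match(edges$id_b, nodes$id)]
  edges$yend <- nodes$y[match(edges$id_b, nodes$id)]
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    nodes$order <- manifest$order[match(nodes$sample_id, manifest$sample_id)]
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$cosine),
      colour = "grey40") +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
  if (!is.null(manifest)) {
    p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$order), size = 2)
  } else {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y), size = 2)
  }
}

#' Plot cluster/order composition
#'
#' Stacked bar chart of the order make-up of each cluster, the graphical
#' counterpart of [summarize_clusters()].
#'
#' @param composition Tibble from [summarize_clusters()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$cluster_id, y = .data$count,
                               fill = .data$order)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "fingerprints") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
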