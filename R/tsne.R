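#' Deterministic t-SNE embedding of a similarity matrix
#'
#' Embeds the dissimilarity `d = 1 - cosine` in 2-D by t-distributed
#' stochastic neighbour embedding. The implementation is fully
#' deterministic: the layout is initialised from the top two principal
#' axes of the double-centred similarity matrix (no random restarts), so
#' identical inputs give identical coordinates; `seed` is recorded in the
#' returned parameters for provenance. Sub-threshold pairs are not pruned:
#' the embedding sees the complete dissimilarity structure, thresholding
#' applies to the network only.
#'
#' @param matrix A [similarity_matrix()].
#' @param perplexity Target perplexity (effective neighbour count);
#'   automatically clipped to `(n - 1) / 3`.
#' @param seed Integer recorded in the embedding parameters.
#' @param learning_rate,n_iter,early_exaggeration Gradient-descent
#'   settings; early exaggeration multiplies the attractive forces for the
#'   first quarter of the iterations. The default learning rate is the
#'   "auto" rule `max(n / early_exaggeration, 10)`, which keeps the
#'   optimisation stable on the small panels this package embeds.
#' @return A `fingerprint_embedding`: list with `ids`, `coordinates`
#'   (n x 2, centred on the origin), and `params`.
#' @export
tsne_embed <- function(matrix, perplexity = 15, seed = 42L,
                       learning_rate = NULL, n_iter = 1000L,
                       early_exaggeration = 12) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  n <- nrow(matrix$scores)
  if (n < 4L) {
    abort("t-SNE needs at least 4 fingerprints; plot the network directly instead.",
          class = "fingernet_bad_param")
  }
  perp <- min(perplexity, (n - 1) / 3)
  learning_rate <- learning_rate %||% max(n / early_exaggeration, 10)
  d2 <- (1 - matrix$scores)^2
  diag(d2) <- 0
  P <- cond_probabilities(d2, perp)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  # deterministic initialisation: top-2 principal axes of the
  # double-centred similarity matrix, canonical signs, scaled to sd 1e-4
  Hc <- diag(n) - 1 / n
  B <- Hc %*% matrix$scores %*% Hc
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  Y <- eig$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[1:2], 0)), 2L)
  for (c in 1:2) {
    peak <- which.max(abs(Y[, c]))
    if (length(peak) && Y[peak, c] < 0) Y[, c] <- -Y[, c]
  }
  s0 <- stats::sd(as.vector(Y))
  if (is.finite(s0) && s0 > 0) Y <- Y / s0 * 1e-4

  exag_until <- max(1L, floor(n_iter / 4))
  gains <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  eps <- 1e-12
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= exag_until) P * early_exaggeration else P
    # pairwise Student-t kernel in the embedding
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), eps)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= exag_until) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8),
                  0.01)
    inc <- momentum * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  structure(
    list(ids = matrix$ids,
         coordinates = Y,
         params = list(perplexity = perp, learning_rate = learning_rate,
                       iterations = as.integer(n_iter),
                       early_exaggeration = early_exaggeration,
                       seed = as.integer(seed))),
    class = "fingerprint_embedding"
  )
}

# Row-conditional affinities at a fixed perplexity: for each row a binary
# search on the Gaussian precision beta matches the entropy to
# log(perplexity).
cond_probabilities <- function(d2, perplexity, tol = 1e-7, max_iter = 100L) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- rep(0, length(di)) }
      else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      err <- H - target
      if (abs(err) < tol) break
      if (err > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' @export
print.fingerprint_embedding <- function(x, ...) {
  cat(sprintf("<fingerprint_embedding> %d fingerprints, perplexity %g\n",
              nrow(x$coordinates), x$params$perplexity))
  invisible(x)
}

#' @describeIn tsne_embed Coordinates as a tibble
#'   (`sample_id`, `replicate_id`, `x`, `y`).
#' @param x A `fingerprint_embedding`.
#' @param ... Unused.
#' @export
tidy.fingerprint_embedding <- function(x, ...) {
  coords <- x$coordinates
  tibble::tibble(sample_id = x$ids$sample_id,
                 replicate_id = x$ids$replicate_id,
                 x = coords[, 1L],
                 y = coords[, 2L])
}

#' Trustworthiness of an embedding
#'
#' Measures how much the k-nearest-neighbour structure of the embedding can
#' be trusted: 1 minus the normalised penalty over points that are embedded
#' neighbours without being neighbours in the original dissimilarity.
#'
#' @param dissimilarity n x n dissimilarity matrix of the original space.
#' @param coordinates n x 2 embedded coordinates.
#' @param k Neighbourhood size.
#' @return Trustworthiness in \[0, 1\].
#' @export
embedding_trustworthiness <- function(dissimilarity, coordinates, k = 5L) {
  n <- nrow(dissimilarity)
  stopifnot(n == nrow(coordinates), k < n / 2)
  emb_d <- as.matrix(stats::dist(coordinates))
  penalty <- 0
  for (i in seq_len(n)) {
    orig_rank <- rank(dissimilarity[i, -i], ties.method = "first")
    others <- seq_len(n)[-i]
    knn_orig <- others[orig_rank <= k]
    knn_emb <- others[order(emb_d[i, -i])[seq_len(k)]]
    extra <- setdiff(knn_emb, knn_orig)
    if (length(extra)) {
      penalty <- penalty +
        sum(orig_rank[match(extra, others)] - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * penalty
}
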