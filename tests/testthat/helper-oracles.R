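# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal implementation available so the package's
# vectorised versions are checked against something that shares no code
# with them.

# SNIP by two explicit loops over points and clipping windows.
snip_oracle <- function(y, iterations, decreasing = TRUE) {
  n <- length(y)
  b <- y
  ks <- if (decreasing) iterations:1 else 1:iterations
  for (k in ks) {
    b_new <- b
    for (i in seq_len(n)) {
      left <- b[max(i - k, 1)]
      right <- b[min(i + k, n)]
      b_new[i] <- min(b[i], (left + right) / 2)
    }
    b <- b_new
  }
  b
}

# Savitzky-Golay by an explicit least-squares fit in every window,
# truncated at the edges, evaluated at the window centre.
sg_oracle <- function(y, half_window, poly_order) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_window)
    hi <- min(n, i + half_window)
    x <- (lo:hi) - i
    fit <- lm.fit(outer(x, 0:poly_order, `^`), y[lo:hi])
    out[i] <- fit$coefficients[[1]]
  }
  out
}

# Maximum-weight one-to-one matching by exhaustive recursion (for peak
# lists of <= ~6 peaks) and the cosine it implies.
exhaustive_cosine <- function(a, b, tol) {
  na <- length(a$mz); nb <- length(b$mz)
  best <- 0
  recurse <- function(i, used_b, acc) {
    if (i > na) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(i + 1L, used_b, acc)  # leave peak i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(a$mz[i] - b$mz[j]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, acc + a$intensity[i] * b$intensity[j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), 0)
  best / (sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2)))
}

# Connected components by breadth-first traversal over an adjacency list.
components_oracle <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$id_a[k]; b <- edges$id_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    queue <- start
    members <- character()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v %in% members) next
      members <- c(members, v)
      queue <- c(queue, setdiff(adj[[v]], members))
    }
    comp[members] <- members[which.min(match(members, nodes))]
  }
  comp
}

# Trustworthiness by the direct rank formula.
trustworthiness_oracle <- function(d_high, coords, k) {
  n <- nrow(d_high)
  d_low <- as.matrix(dist(coords))
  pen <- 0
  for (i in seq_len(n)) {
    oth <- setdiff(seq_len(n), i)
    rk <- rank(d_high[i, oth], ties.method = "first")
    nn_high <- oth[rk <= k]
    nn_low <- oth[order(d_low[i, oth])[1:k]]
    for (j in setdiff(nn_low, nn_high)) {
      pen <- pen + (rk[match(j, oth)] - k)
    }
  }
  unname(1 - 2 * pen / (n * k * (2 * n - 3 * k - 1)))
}

# Random small peak list on a given m/z interval.
random_peaklist <- function(n, lo = 400, hi = 2000, mode = "lipid",
                            id = "rnd", rep = 1L, min_gap = 1) {
  mz <- sort(runif(n, lo, hi))
  while (any(diff(mz) < min_gap)) mz <- sort(runif(n, lo, hi))
  peaklist(mz, runif(n, 0.1, 1), id, rep, mode = mode)
}
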