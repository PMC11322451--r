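# Brute-force oracles, independent of the package implementation.
# All graph oracles enumerate simple paths / triangles directly and are
# only meant for graphs with <= ~7 nodes.

# every simple path s -> t as a list of node index vectors
enumerate_paths <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  out
}

path_len <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- enumerate_paths(W, s, t)
    if (length(paths)) D[s, t] <- min(vapply(paths, path_len, 0, W = W))
  }
  D
}

oracle_betweenness <- function(W, normalized = TRUE) {
  n <- nrow(W)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_paths(W, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, path_len, 0, W = W)
    short <- paths[lens <= min(lens) * (1 + 1e-12)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(short, function(p) v %in% p, TRUE))
      b[v] <- b[v] + thru / length(short)
    }
  }
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (Wh[i, j] * Wh[j, h] * Wh[h, i])^(1 / 3)
    }
    C[i] <- acc / (k * (k - 1))
  }
  C
}

oracle_global_eff <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_cpl <- function(W) {
  D <- oracle_distances(W)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_local_eff <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(W[i, ] > 0)
    if (length(nbrs) < 2) next
    out[i] <- oracle_global_eff(W[nbrs, nbrs, drop = FALSE])
  }
  out
}

random_test_graph <- function(n, p_edge = 0.6) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- ifelse(stats::runif(sum(ut)) < p_edge, stats::runif(sum(ut), 0.1, 2), 0)
  W[ut] <- vals
  W + t(W)
}

# Benjamini-Hochberg step-up by the textbook recipe
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- prev
  }
  pmin(q, 1)
}

# exhaustive sign-flip p by direct enumeration with the longhand t formula
oracle_signflip_p <- function(d) {
  n <- length(d)
  tstat <- function(x) {
    s <- stats::sd(x)
    if (s == 0) {
      if (mean(x) == 0) 0 else sign(mean(x)) * Inf
    } else mean(x) / (s / sqrt(n))
  }
  t_obs <- tstat(d)
  hits <- 0
  for (k in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(k, 2^(0:(n - 1))) > 0, -1, 1)
    if (abs(tstat(signs * d)) >= abs(t_obs) - 1e-12 * max(1, abs(t_obs)))
      hits <- hits + 1
  }
  hits / 2^n
}

# small toy parcellation without a volume, for side-flip/classification tests
toy_parcellation <- function(n_side = 2, n_mid = 1) {
  labels <- data.frame(
    id = seq_len(2 * n_side + n_mid),
    name = c(sprintf("L%03d", seq_len(n_side)), sprintf("R%03d", seq_len(n_side)),
             if (n_mid > 0) sprintf("M%03d", seq_len(n_mid))),
    side = c(rep("left", n_side), rep("right", n_side),
             if (n_mid > 0) rep("midline", n_mid)),
    groups = "", stringsAsFactors = FALSE)
  connremod:::new_parcellation(labels)
}

named_matrix <- function(vals, names) {
  m <- matrix(vals, length(names), length(names), dimnames = list(names, names))
  m
}
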