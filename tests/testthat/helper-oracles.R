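# Independent oracles, kept free of the package's own code paths.

# all-pairs shortest paths by exhaustive relaxation (Floyd-Warshall)
fwDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dimnames(d) <- dimnames(adj)
  d
}

# random simple undirected graph as an adjacency matrix + igraph twin
randomGraph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  adj
}

adjToNetwork <- function(adj) {
  GeneNetwork(igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
}

# pooled-variance two-sample t statistic, straight from the formula
pooledT <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# tiny expression bundle built by hand
tinyBundle <- function(mat, calls = NULL, conditions = NULL) {
  if (is.null(calls))
    calls <- matrix("P", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (is.null(conditions))
    conditions <- rep(c("control", "stress"), each = ncol(mat) / 2)
  ExpressionBundle(mat, calls, conditions)
}
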