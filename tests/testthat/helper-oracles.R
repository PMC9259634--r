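# Shared fixtures and independent oracles used across the test files.

library(igraph)

star7 <- function() as_spatial_graph(make_star(7, mode = "undirected"))
path_graph <- function(n) as_spatial_graph(make_ring(n, circular = FALSE))
complete <- function(n) as_spatial_graph(make_full_graph(n))
cycle <- function(n) as_spatial_graph(make_ring(n))

# brute-force all-pairs shortest paths (Floyd-Warshall), independent of igraph
fw_mean_path <- function(g) {
  A <- as.matrix(as_adjacency_matrix(g, sparse = FALSE))
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  mean(D[upper.tri(D)])
}

# hand oracle for Q_ST: explicit population variances
qst_oracle <- function(sample) {
  sample <- sample[lengths(sample) > 0]
  means <- sapply(sample, mean)
  s2b <- mean((means - mean(means))^2)
  s2w <- mean(sapply(sample, function(x) mean((x - mean(x))^2)))
  s2b / (s2b + s2w)
}

# directed-edge Pearson assortativity computed from first principles
assortativity_oracle <- function(g, theta_v) {
  el <- as_edgelist(g, names = FALSE)
  x <- c(theta_v[el[, 1]], theta_v[el[, 2]])
  y <- c(theta_v[el[, 2]], theta_v[el[, 1]])
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all +/-theta labelings of M vertices with both types present
all_two_type_labelings <- function(M, theta = 0.5) {
  grids <- expand.grid(rep(list(c(-theta, theta)), M))
  grids <- grids[apply(grids, 1, function(r) length(unique(r)) == 2), , drop = FALSE]
  lapply(seq_len(nrow(grids)), function(i) as.numeric(grids[i, ]))
}

balanced_labelings <- function(M, theta = 0.5) {
  Filter(function(v) sum(v > 0) == M / 2, all_two_type_labelings(M, theta))
}
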