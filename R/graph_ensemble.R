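#' Enumerate all connected graphs on M vertices up to isomorphism
#'
#' Generates every undirected connected graph on `M` unlabeled vertices,
#' one canonical representative per isomorphism class. Enumeration proceeds
#' by vertex augmentation: the isomorphism classes of all graphs on m
#' vertices are extended by a new vertex attached to every subset of the
#' existing vertices, and candidates are deduplicated through a canonical
#' labeling (BLISS, via \pkg{igraph}). Connectivity is imposed only at the
#' final size, since a connected graph may lose connectivity when a vertex
#' is removed. Counts match the sequence 1, 1, 2, 6, 21, 112, 853, ... of
#' connected graphs (OEIS A001349).
#'
#' @param M Number of vertices, 1 <= M <= 9. M = 8 takes a few minutes,
#'   M = 9 substantially longer; M <= 7 is the intended working range.
#' @return List of igraph objects, each with a `name` attribute
#'   `"M<M>_g<index>"`, ordered by edge count then canonical form.
#' @export
enumerate_connected_graphs <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M != round(M) || M < 1 || M > 9)
    stop("'M' must be a single integer between 1 and 9")
  M <- as.integer(M)
  cached <- .enumeration_cache[[as.character(M)]]
  if (!is.null(cached)) return(cached)
  # adjacency matrices of all graphs (connected or not) on m vertices, up to iso
  reps <- list(matrix(0, 1, 1))
  m <- 1L
  while (m < M) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    nxt <- vector("list", 0L)
    subsets <- expand.grid(rep(list(c(0, 1)), m))
    for (A in reps) {
      for (r in seq_len(nrow(subsets))) {
        row <- as.numeric(subsets[r, ])
        B <- rbind(cbind(A, row), c(row, 0))
        dimnames(B) <- NULL
        key <- canonical_key(B)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- canonical_adjacency(B)
        }
      }
    }
    reps <- nxt
    m <- m + 1L
  }
  graphs <- lapply(reps, igraph::graph_from_adjacency_matrix, mode = "undirected")
  graphs <- Filter(igraph::is_connected, graphs)
  ord <- order(vapply(graphs, function(g) as.integer(igraph::ecount(g)), integer(1)),
               vapply(graphs, function(g) canonical_key(as_adjacency(g)), character(1)))
  graphs <- graphs[ord]
  for (i in seq_along(graphs))
    graphs[[i]] <- igraph::set_graph_attr(graphs[[i]], "name", sprintf("M%d_g%d", M, i))
  .enumeration_cache[[as.character(M)]] <- graphs
  graphs
}

# per-session cache: the ensemble for a given M is deterministic
.enumeration_cache <- new.env(parent = emptyenv())

as_adjacency <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  dimnames(A) <- NULL
  A
}

canonical_adjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  perm <- igraph::canonical_permutation(g)$labeling
  as_adjacency(igraph::permute(g, perm))
}

canonical_key <- function(A) {
  B <- canonical_adjacency(A)
  paste(B[upper.tri(B)], collapse = "")
}

#' Stratified sample of a graph ensemble
#'
#' Samples without replacement at most `per_stratum` graphs from each
#' stratum of an ensemble, strata being the edge-count classes (the only
#' integer graph invariant that varies within a fixed-M ensemble). Used to
#' keep large ensembles representative while bounding computation.
#'
#' @param graphs List of igraph landscapes.
#' @param per_stratum Maximum number of graphs retained per edge-count class.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return Sub-list of `graphs` ordered by edge count.
#' @export
stratified_graph_sample <- function(graphs, per_stratum, seed) {
  stopifnot(length(graphs) > 0L, per_stratum >= 1L)
  edges <- vapply(graphs, function(g) as.integer(igraph::ecount(g)), integer(1))
  idx <- integer(0)
  with_seed(seed, {
    for (e in sort(unique(edges))) {
      pool <- which(edges == e)
      take <- min(per_stratum, length(pool))
      idx <- c(idx, sort(sample_int(pool, take)))
    }
  })
  graphs[idx]
}

#' Stratified sample of two-type habitat assignments for a graph
#'
#' Draws random two-type (-theta / +theta) habitat assignments for the
#' vertices of a graph and returns a subset stratified by the quartiles of
#' their habitat assortativity, at most `n_per_stratum` per quartile. This
#' yields labelings spanning the attainable assortativity range rather than
#' clustering at typical values. Assignments in which all vertices share one
#' type are rejected (assortativity undefined there).
#'
#' @param g An igraph landscape.
#' @param theta Habitat heterogeneity; vertices get optimum -theta or +theta.
#' @param n_per_stratum Maximum labelings per assortativity quartile.
#' @param seed Integer seed.
#' @param pool_size Number of random assignments drawn before
#'   stratification; for small graphs the pool is the full set of distinct
#'   non-constant assignments.
#' @return List of per-vertex optimum vectors; each element carries an
#'   `r_theta` attribute with its assortativity. The list carries attribute
#'   `n_strata` (the number of distinct quartile strata realised; 1 when the
#'   graph's symmetry forces a single assortativity value).
#' @export
sample_habitat_assignments <- function(g, theta, n_per_stratum, seed, pool_size = 256L) {
  validate_spatial_graph(g)
  stopifnot(theta > 0, n_per_stratum >= 1L)
  M <- igraph::vcount(g)
  if (M < 2L) stop("habitat sampling needs at least two vertices")
  out <- with_seed(seed, {
    if (2^M - 2 <= pool_size) {
      # exhaustive pool of non-constant assignments
      pool <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), M)))
      pool <- pool[rowSums(pool) %in% seq_len(M - 1L), , drop = FALSE]
    } else {
      pool <- matrix(stats::runif(pool_size * M) < 0.5, ncol = M)
      keep <- rowSums(pool) %in% seq_len(M - 1L)
      pool <- unique(pool[keep, , drop = FALSE])
    }
    r <- apply(pool, 1L, function(tp) habitat_assortativity(g, ifelse(tp, theta, -theta)))
    qs <- stats::quantile(r, probs = seq(0, 1, 0.25), names = FALSE)
    breaks <- unique(qs)
    if (length(breaks) == 1L) {
      strata <- rep(1L, length(r))
    } else {
      strata <- cut(r, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    }
    chosen <- integer(0)
    for (s in sort(unique(strata))) {
      pool_s <- which(strata == s)
      take <- min(n_per_stratum, length(pool_s))
      chosen <- c(chosen, sample_int(pool_s, take))
    }
    labs <- lapply(chosen, function(i) {
      v <- ifelse(pool[i, ], theta, -theta)
      attr(v, "r_theta") <- r[i]
      v
    })
    attr(labs, "n_strata") <- length(unique(strata))
    labs
  })
  out
}

# sample() with the surprising length-1 behaviour removed
sample_int <- function(x, size) {
  if (length(x) == 1L) return(rep(x, length.out = size))
  sample(x, size)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
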