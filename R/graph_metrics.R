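#' Degree homogeneity of a landscape graph
#'
#' Computes \eqn{h_d = \langle\sqrt k\rangle^2 / \langle k\rangle}, the
#' squared mean root degree over the mean degree. By the Cauchy-Schwarz
#' inequality \eqn{h_d \le 1}, with equality exactly for regular graphs, so
#' h_d measures homogeneity in vertex connectivity. Under the degree-based
#' mean-field approximation the equilibrium mean population size at full
#' migration is \eqn{bK h_d}, which is how h_d enters the differentiation
#' analysis: irregular graphs depress population sizes and amplify drift.
#'
#' @param g An igraph landscape (connected, no isolated vertices).
#' @return h_d in (0, 1].
#' @export
degree_homogeneity <- function(g) {
  validate_spatial_graph(g)
  k <- igraph::degree(g)
  if (igraph::vcount(g) > 1L && any(k == 0)) stop("graph has an isolated vertex")
  if (igraph::vcount(g) == 1L) return(1)
  mean(sqrt(k))^2 / mean(k)
}

#' Average shortest-path length
#'
#' Mean of the shortest-path distances over all unordered vertex pairs; a
#' high value means low landscape connectivity and stronger isolation of
#' local populations.
#'
#' @param g A connected igraph landscape with at least 2 vertices.
#' @return Mean path length >= 1.
#' @export
mean_path_length <- function(g) {
  validate_spatial_graph(g)
  if (igraph::vcount(g) < 2L) stop("mean path length needs at least two vertices")
  igraph::mean_distance(g, directed = FALSE)
}

#' Habitat assortativity of a labeled landscape
#'
#' Pearson correlation of the habitat values found at the two endpoints of
#' each edge, with every undirected edge contributing both orientations so
#' the measure is symmetric. r = -1 means every edge joins dissimilar
#' habitats (disassortative landscape); r -> 1 means the landscape splits
#' into clusters of identical habitat. For balanced two-type labelings this
#' equals 2(P(I,I) - P(I,II)), twice the excess of within-type over
#' between-type edge proportions.
#'
#' @param g An igraph landscape.
#' @param theta_v Numeric per-vertex habitat value (environmental optimum).
#' @return Assortativity in [-1, 1].
#' @export
habitat_assortativity <- function(g, theta_v) {
  validate_spatial_graph(g)
  check_labeling(g, theta_v)
  if (igraph::ecount(g) < 1L) stop("assortativity needs at least one edge")
  if (length(unique(theta_v)) < 2L)
    stop("habitat assortativity is undefined when all habitat values are identical")
  el <- igraph::as_edgelist(g, names = FALSE)
  toe <- c(theta_v[el[, 1]], theta_v[el[, 2]])
  tip <- c(theta_v[el[, 2]], theta_v[el[, 1]])
  if (stats::sd(toe) == 0)
    stop("habitat assortativity is undefined: zero variance over edge endpoints")
  stats::cor(toe, tip)
}

#' Edge-proportion form of assortativity for two-type labelings
#'
#' For a two-type labeling, returns 2(P(I,I) - P(I,II)) where P(I,I) is the
#' proportion of directed edges joining two type-I vertices and P(I,II) the
#' proportion joining type II to type I. Provided as the combinatorial
#' counterpart of [habitat_assortativity()]; the two coincide exactly when
#' the types hold equal shares of the directed edge endpoints (equal degree
#' sums), the graph analogue of habitats being homogeneously distributed.
#'
#' @inheritParams habitat_assortativity
#' @return A real value in [-1, 1].
#' @export
assortativity_edge_proportions <- function(g, theta_v) {
  validate_spatial_graph(g)
  check_labeling(g, theta_v)
  vals <- sort(unique(theta_v))
  if (length(vals) != 2L) stop("edge-proportion form requires exactly two habitat types")
  type2 <- theta_v == vals[2]
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- c(type2[el[, 1]], type2[el[, 2]])
  b <- c(type2[el[, 2]], type2[el[, 1]])
  p_II_ <- mean(!a & !b)  # both type I
  p_I_II <- mean(!a & b)  # type II tip, type I toe
  2 * (p_II_ - p_I_II)
}

#' Landscape metric table
#'
#' Computes the metric set used by the ensemble meta-analysis for a
#' collection of graphs (optionally labeled): vertex count, edge count,
#' average path length, degree homogeneity and, when labelings are given,
#' habitat assortativity.
#'
#' @param graphs List of igraph landscapes.
#' @param labelings Optional list of per-vertex habitat vectors, parallel to
#'   `graphs`.
#' @param ids Optional character ids; defaults to each graph's `name`
#'   attribute when present (as set by [enumerate_connected_graphs()]), so
#'   that rows can be traced back to the ensemble, else `graph_1`,
#'   `graph_2`, ...
#' @return A data frame with columns `graph_id`, `M`, `edges`,
#'   `mean_path_length`, `h_d` and (if labeled) `r_theta`.
#' @export
graph_metrics_table <- function(graphs, labelings = NULL, ids = NULL) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  if (is.null(ids))
    ids <- vapply(seq_along(graphs), function(i)
      igraph::graph_attr(graphs[[i]], "name") %||% paste0("graph_", i),
      character(1))
  out <- data.frame(
    graph_id = ids,
    M = vapply(graphs, function(g) as.integer(igraph::vcount(g)), integer(1)),
    edges = vapply(graphs, function(g) as.integer(igraph::ecount(g)), integer(1)),
    mean_path_length = vapply(graphs, function(g)
      if (igraph::vcount(g) >= 2) mean_path_length(g) else NA_real_, numeric(1)),
    h_d = vapply(graphs, degree_homogeneity, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(labelings)) {
    stopifnot(length(labelings) == length(graphs))
    out$r_theta <- mapply(habitat_assortativity, graphs, labelings)
  }
  out
}
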