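#' Coerce to a spatial landscape graph
#'
#' A landscape is represented as an undirected, simple, connected
#' \pkg{igraph} graph whose vertices are habitat patches and whose edges
#' constrain migration. This coercer accepts an igraph object, a symmetric
#' 0/1 adjacency matrix, or a two-column edge matrix/data frame (1-based
#' vertex ids), validates the landscape invariants, and returns an igraph
#' object carrying an optional `name` graph attribute.
#'
#' @param x An igraph object, adjacency matrix, or two-column edge table.
#' @param n_vertices Vertex count, required when `x` is an edge table whose
#'   largest id underestimates the number of vertices (isolated vertices are
#'   rejected anyway since the landscape must be connected).
#' @param name Optional character tag stored as the graph `name` attribute.
#' @return An igraph object of class `igraph`.
#' @examples
#' g <- as_spatial_graph(igraph::make_ring(6))
#' degree_homogeneity(g)
#' @export
as_spatial_graph <- function(x, n_vertices = NULL, name = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
  } else if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 2) {
    g <- igraph::graph_from_adjacency_matrix(x, mode = "undirected")
  } else if ((is.matrix(x) || is.data.frame(x)) && ncol(x) == 2) {
    el <- as.matrix(x)
    storage.mode(el) <- "double"
    n <- if (is.null(n_vertices)) max(el) else n_vertices
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
  } else if (is.matrix(x) && nrow(x) == ncol(x)) {
    # small square matrix: ambiguous with an edge table only for 1x1/2x2,
    # which cannot be a connected multi-vertex adjacency anyway
    g <- igraph::graph_from_adjacency_matrix(x, mode = "undirected")
  } else {
    stop("cannot interpret 'x' as a spatial graph")
  }
  validate_spatial_graph(g)
  if (!is.null(name)) g <- igraph::set_graph_attr(g, "name", name)
  g
}

#' Validate landscape invariants
#'
#' Checks that a graph is a valid landscape: undirected, simple (no loops or
#' multi-edges) and connected, with at least one vertex.
#'
#' @param g An igraph object.
#' @return `g`, invisibly; errors otherwise.
#' @export
validate_spatial_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("'g' must be an igraph object")
  if (igraph::is_directed(g)) stop("landscape graph must be undirected")
  if (igraph::vcount(g) < 1L) stop("landscape graph must have at least one vertex")
  if (!igraph::is_simple(g)) stop("landscape graph must be simple (no loops or multi-edges)")
  if (!igraph::is_connected(g)) stop("landscape graph must be connected")
  invisible(g)
}

#' Two-type habitat labeling
#'
#' Builds the per-vertex vector of environmental optima for a two-habitat
#' landscape with symmetric conditions -theta (type I) and +theta (type II).
#'
#' @param types Vector of habitat types, either a logical/0-1 vector
#'   (`TRUE`/1 meaning type II) or a character vector of `"I"`/`"II"`.
#' @param theta Habitat heterogeneity, theta >= 0; type I vertices receive
#'   optimum `-theta` and type II vertices `+theta`.
#' @return Numeric vector of per-vertex environmental optima.
#' @export
two_type_labeling <- function(types, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0)
  if (is.character(types)) {
    if (!all(types %in% c("I", "II"))) stop("character 'types' must be \"I\" or \"II\"")
    types <- types == "II"
  }
  types <- as.logical(types)
  if (anyNA(types)) stop("'types' contains missing values")
  ifelse(types, theta, -theta)
}

check_labeling <- function(g, theta_v) {
  if (!is.numeric(theta_v) || length(theta_v) != igraph::vcount(g))
    stop("habitat labeling must be a numeric vector with one value per vertex")
  invisible(theta_v)
}

#' Read and write landscape graphs as plain-text edge lists
#'
#' The edge-list format has one edge per line as two whitespace-separated
#' 0-based vertex ids; lines starting with `#` are ignored. `write_edgelist()`
#' additionally records the vertex count on a `# M <count>` header line so
#' that graphs survive a round trip.
#'
#' @param path File path.
#' @param g An igraph landscape.
#' @return `read_edgelist()` returns an igraph object; `write_edgelist()`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  header <- grep("^#\\s*M\\s+\\d+", lines, value = TRUE)
  n <- if (length(header)) as.integer(sub("^#\\s*M\\s+(\\d+).*$", "\\1", header[1])) else NULL
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    if (is.null(n)) stop("empty edge list and no '# M' header")
    return(as_spatial_graph(igraph::make_empty_graph(n, directed = FALSE)))
  }
  el <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  if (ncol(el) != 2L) stop("edge list lines must contain exactly two vertex ids")
  as_spatial_graph(el + 1L, n_vertices = if (is.null(n)) max(el) + 1L else n)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(g, path) {
  validate_spatial_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M %d", igraph::vcount(g)), con)
  writeLines(sprintf("%d %d", el[, 1], el[, 2]), con)
  invisible(path)
}

#' Read and write habitat labelings as CSV
#'
#' Labelings are stored as a CSV with columns `vertex` (0-based id) and
#' `theta` (environmental optimum).
#'
#' @param path File path.
#' @param theta_v Numeric per-vertex optimum vector.
#' @return `read_labeling()` returns the numeric theta vector ordered by
#'   vertex id; `write_labeling()` returns `path` invisibly.
#' @export
read_labeling <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("vertex", "theta") %in% names(df))) stop("labeling CSV needs columns 'vertex' and 'theta'")
  df$theta[order(df$vertex)]
}

#' @rdname read_labeling
#' @export
write_labeling <- function(theta_v, path) {
  utils::write.csv(
    data.frame(vertex = seq_along(theta_v) - 1L, theta = theta_v),
    path, row.names = FALSE
  )
  invisible(path)
}
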