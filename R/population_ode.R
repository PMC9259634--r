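#' Deterministic population-size dynamics on a graph
#'
#' Right-hand side of the deterministic approximation of the metapopulation
#' size under no selection:
#' \deqn{dN^{(i)}/dt = N^{(i)}[b(1-m) - N^{(i)}/K] + m b \sum_{j \ne i} (a_{ij}/d_j) N^{(j)}}
#' Logistic growth of the non-migrating fraction plus migration gains routed
#' through the random-walk kernel a_ij / d_j.
#'
#' @param N Numeric vector of per-vertex population sizes (>= 0).
#' @param g An igraph landscape.
#' @param params A [sim_params()] object (only `b`, `K`, `m` are used).
#' @return Numeric vector dN/dt.
#' @export
ode_rhs <- function(N, g, params) {
  stopifnot(length(N) == igraph::vcount(g))
  A <- as_adjacency(g)
  k <- igraph::degree(g)
  inflow <- if (igraph::vcount(g) > 1L) as.numeric(A %*% (N / k)) else 0
  N * (params$b * (1 - params$m) - N / params$K) + params$m * params$b * inflow
}

#' Equilibrium of the deterministic population dynamics
#'
#' Integrates the population-size equation from the uniform state N = K
#' until the residual drops below `tol` (sup-norm of dN/dt relative to bK),
#' and returns the equilibrium, its vertex mean, and the degree-homogeneity
#' prediction for comparison. On irregular graphs highly connected vertices
#' equilibrate above bK (oversaturated carrying capacity) while the mean
#' over vertices falls below bK.
#'
#' @param g An igraph landscape.
#' @param params A [sim_params()] object.
#' @param tol Convergence tolerance on `max |dN/dt| / (bK)`.
#' @param t_max Maximum integration time before giving up.
#' @return List with `N` (per-vertex equilibrium), `N_bar` (vertex mean),
#'   `h_d`, `prediction_mean_field` (the mean-field N_bar at the same m)
#'   and `residual`.
#' @export
solve_equilibrium <- function(g, params, tol = 1e-10, t_max = 1e5) {
  validate_spatial_graph(g)
  bK <- params$b * params$K
  deriv <- function(t, N, parms) list(ode_rhs(pmax(N, 0), g, params))
  N <- rep(params$K, igraph::vcount(g))
  t_done <- 0
  chunk <- 50
  repeat {
    res <- max(abs(ode_rhs(N, g, params))) / bK
    if (res < tol) break
    if (t_done >= t_max)
      stop(sprintf("equilibrium not reached by t = %g (residual %.3g)", t_max, res))
    sol <- deSolve::ode(y = N, times = c(0, chunk), func = deriv, method = "lsoda")
    N <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    t_done <- t_done + chunk
  }
  list(N = N, N_bar = mean(N),
       h_d = degree_homogeneity(g),
       prediction_mean_field = mean_field_equilibrium(igraph::degree(g), params),
       residual = res)
}

#' Degree-based mean-field equilibrium population size
#'
#' Mean equilibrium population size under the degree-class ("mean-field")
#' reduction, which assumes all vertices of equal degree are statistically
#' equivalent and the graph is uncorrelated. At full migration (m = 1) the
#' closed form is \eqn{\bar N = bK \langle\sqrt k\rangle^2/\langle k\rangle
#' = bK h_d}; for m < 1 the stationary degree-class system
#' \deqn{0 = \bar N^{(k)}[b(1-m) - \bar N^{(k)}/K] + m b (k/\langle k\rangle)\bar N}
#' is solved by damped fixed-point iteration on \eqn{\bar N = \sum_k P(k)
#' \bar N^{(k)}} (each class equation is a quadratic solved exactly given
#' \eqn{\bar N}).
#'
#' @param degrees Integer vector of vertex degrees (the empirical degree
#'   distribution), or a two-column matrix/data frame of `(k, P(k))`.
#' @param params A [sim_params()] object.
#' @param tol Fixed-point tolerance for the m < 1 case.
#' @return The mean-field mean population size.
#' @export
mean_field_equilibrium <- function(degrees, params, tol = 1e-12) {
  if (is.matrix(degrees) || is.data.frame(degrees)) {
    degrees <- as.data.frame(degrees)
    k <- as.numeric(degrees[[1]])
    Pk <- as.numeric(degrees[[2]])
    Pk <- Pk / sum(Pk)
  } else {
    tab <- table(degrees)
    k <- as.numeric(names(tab))
    Pk <- as.numeric(tab) / length(degrees)
  }
  if (any(k <= 0)) stop("degree distribution contains non-positive degrees")
  b <- params$b; K <- params$K; m <- params$m
  kbar <- sum(Pk * k)
  if (m == 0) return(b * K)
  if (m == 1) return(b * K * sum(Pk * sqrt(k))^2 / kbar)
  # stationary class sizes given N_bar: positive root of
  # N_k^2/K - b(1-m) N_k - m b (k/<k>) N_bar = 0
  class_sizes <- function(N_bar) {
    disc <- (b * (1 - m))^2 + 4 * m * b * (k / kbar) * N_bar / K
    K / 2 * (b * (1 - m) + sqrt(disc))
  }
  N_bar <- b * K
  for (it in seq_len(10000L)) {
    N_new <- sum(Pk * class_sizes(N_bar))
    step <- 0.5 * (N_new - N_bar)  # damping
    N_bar <- N_bar + step
    if (abs(step) < tol * b * K) return(N_bar)
  }
  stop("mean-field fixed point did not converge")
}
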