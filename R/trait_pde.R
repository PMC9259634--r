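#' Discretised adaptive-trait axis
#'
#' Uniform grid on the trait interval [-L, L] used by the finite-difference
#' solver for the deterministic trait-distribution dynamics. The default
#' half-width `L = 4 theta + 10 sigma_mu` keeps the support of the steady
#' densities far from the boundary (border densities are checked against a
#' guard during solves).
#'
#' @param params A [sim_params()] object (for the default domain width).
#' @param L Domain half-width; overrides the default.
#' @param n_points Number of grid points (odd keeps s = 0 on the grid).
#' @return List with `s` (grid nodes), `ds` (spacing) and `n_points`.
#' @export
trait_grid <- function(params, L = NULL, n_points = 501L) {
  if (is.null(L)) L <- 4 * params$theta + 10 * params$sigma_mu
  stopifnot(L > 0, n_points >= 11L)
  s <- seq(-L, L, length.out = n_points)
  list(s = s, ds = s[2] - s[1], n_points = as.integer(n_points))
}

# Second difference of q in conservative (flux) form with no-flux
# boundaries: sum(d2 * ds) == 0 exactly, so the mutation operator conserves
# total mass under the Riemann quadrature used for population sizes.
second_diff_noflux <- function(q, ds) {
  n <- length(q)
  flux <- diff(q) / ds            # F_{i+1/2}, zero outside the domain
  (c(flux, 0) - c(0, flux)) / ds
}

grid_mass <- function(n, ds) ds * colSums(n)

#' Trait-dependent birth-rate profile of a habitat
#'
#' @param s Grid of trait values.
#' @param theta_i Environmental optimum of the habitat/vertex.
#' @param params A [sim_params()] object.
#' @param clamp Clamp negative rates at zero (the individual-level rule,
#'   and the default). The raw parabola is negative far from the optimum;
#'   used as a coefficient of the mutation (diffusion) term it would act as
#'   anti-diffusion and make the dynamics ill-posed at the domain edges, so
#'   the clamped profile is the correct deterministic image of the
#'   individual-level rates.
#' @return Numeric vector max(0, b(1 - p(s - theta_i)^2)) (or the raw
#'   parabola when `clamp = FALSE`).
#' @export
birth_profile <- function(s, theta_i, params, clamp = TRUE) {
  v <- params$b * (1 - params$p * (s - theta_i)^2)
  if (clamp) pmax(0, v) else v
}

#' Right-hand side of the two-habitat trait-distribution dynamics
#'
#' The mean-field reduction for balanced two-type landscapes: all vertices
#' of one habitat type share a density \eqn{\bar n^I(s)}, and migrants mix
#' across habitats with weights set by the habitat assortativity,
#' \eqn{(1 - r_\Theta)/2} crossing and \eqn{(1 + r_\Theta)/2} staying:
#' \deqn{\partial_t \bar n^I = \bar n^I [b^I(s)(1-m) - N^I/K]
#'   + \tfrac{1}{2}\mu\sigma_\mu^2 \Delta_s(b^I \bar n^I)
#'   + \tfrac{m}{2}[(1-r_\Theta) b^{II} \bar n^{II} + (1+r_\Theta) b^I \bar n^I]}
#' and symmetrically for habitat II (optima are -theta for I, +theta for
#' II).
#'
#' @param n Matrix `n_points x 2` of densities (columns: habitat I, II).
#' @param r_theta Habitat assortativity in [-1, 1].
#' @param params A [sim_params()] object.
#' @param grid A [trait_grid()].
#' @return Matrix of time derivatives, same shape as `n`.
#' @export
pde_rhs_two_habitat <- function(n, r_theta, params, grid) {
  stopifnot(r_theta >= -1, r_theta <= 1, is.matrix(n), ncol(n) == 2L)
  bI <- birth_profile(grid$s, -params$theta, params)
  bII <- birth_profile(grid$s, params$theta, params)
  N <- grid_mass(n, grid$ds)
  D <- 0.5 * params$mu * params$sigma_mu^2
  m <- params$m
  dI <- n[, 1] * (bI * (1 - m) - N[1] / params$K) +
    D * second_diff_noflux(bI * n[, 1], grid$ds) +
    (m / 2) * ((1 - r_theta) * bII * n[, 2] + (1 + r_theta) * bI * n[, 1])
  dII <- n[, 2] * (bII * (1 - m) - N[2] / params$K) +
    D * second_diff_noflux(bII * n[, 2], grid$ds) +
    (m / 2) * ((1 - r_theta) * bI * n[, 1] + (1 + r_theta) * bII * n[, 2])
  cbind(dI, dII, deparse.level = 0)
}

#' Right-hand side of the per-vertex trait-distribution dynamics
#'
#' Deterministic approximation of the trait densities on the full graph:
#' \deqn{\partial_t n^{(i)}(s) = n^{(i)}[b^{(i)}(s)(1-m) - N^{(i)}/K]
#'   + m \sum_{j\ne i} b^{(j)}(s) (a_{ij}/d_j) n^{(j)}(s)
#'   + \tfrac{1}{2}\mu\sigma_\mu^2 \Delta_s(b^{(i)} n^{(i)})}
#'
#' @param n Matrix `n_points x M` of per-vertex densities.
#' @param g An igraph landscape.
#' @param theta_v Per-vertex environmental optimum.
#' @param params A [sim_params()] object.
#' @param grid A [trait_grid()].
#' @return Matrix of time derivatives, same shape as `n`.
#' @export
pde_rhs_graph <- function(n, g, theta_v, params, grid) {
  M <- igraph::vcount(g)
  stopifnot(is.matrix(n), ncol(n) == M)
  check_labeling(g, theta_v)
  A <- as_adjacency(g)
  k <- igraph::degree(g)
  bmat <- vapply(theta_v, function(th) birth_profile(grid$s, th, params),
                 numeric(grid$n_points))
  N <- grid_mass(n, grid$ds)
  D <- 0.5 * params$mu * params$sigma_mu^2
  m <- params$m
  bn <- bmat * n
  inflow <- bn %*% t(A / outer(rep(1, M), k))      # sum_j b_j n_j a_ij / d_j
  out <- n * (sweep(bmat * (1 - m), 2, N / params$K, function(b, nk) b - nk)) +
    m * inflow +
    D * apply(bn, 2, second_diff_noflux, ds = grid$ds)
  out
}

#' Moments and differentiation of a density state
#'
#' Per-column (habitat or vertex) population sizes, density-weighted trait
#' means and variances, and the adaptive differentiation Q_ST,s formed from
#' the unweighted between-column variance of the means over between plus
#' the mean within-column variance (mirroring the conventions of [qst()]).
#'
#' @param n Matrix `n_points x ncol` of non-negative densities.
#' @param grid A [trait_grid()].
#' @return List with `N` (masses), `mean_s`, `var_s`, `qst_s` and `N_bar`.
#' @export
density_summary <- function(n, grid) {
  n <- pmax(n, 0)
  N <- grid_mass(n, grid$ds)
  mean_s <- colSums(n * grid$s) * grid$ds / N
  var_s <- vapply(seq_len(ncol(n)), function(j)
    sum(n[, j] * (grid$s - mean_s[j])^2) * grid$ds / N[j], numeric(1))
  sigma2_B <- mean((mean_s - mean(mean_s))^2)
  sigma2_W <- mean(var_s)
  qst_s <- if (sigma2_B + sigma2_W == 0) NA_real_ else sigma2_B / (sigma2_B + sigma2_W)
  list(N = N, N_bar = mean(N), mean_s = mean_s, var_s = var_s, qst_s = qst_s)
}

#' Default initial density state
#'
#' Gaussian bump at s = 0 with standard deviation sigma_mu and mass K per
#' column, mirroring the initial condition of the individual-based
#' simulations.
#'
#' @param grid A [trait_grid()].
#' @param params A [sim_params()] object.
#' @param n_cols Number of columns (habitats or vertices).
#' @return Matrix `n_points x n_cols`.
#' @export
initial_density <- function(grid, params, n_cols = 2L) {
  g0 <- stats::dnorm(grid$s, 0, params$sigma_mu)
  g0 <- g0 / (sum(g0) * grid$ds) * params$K
  matrix(rep(g0, n_cols), ncol = n_cols)
}

#' Integrate trait-distribution dynamics to steady state
#'
#' Method-of-lines integration (adaptive \code{lsoda}) of a density system
#' until the sup-norm of the time derivative falls below `tol`. Positivity
#' is monitored: densities more negative than a small tolerance abort the
#' solve, and tiny negative undershoots are clipped. A border guard warns
#' when the boundary density exceeds 1e-8 of the peak (domain too narrow).
#'
#' @param rhs Function `n -> dn/dt` operating on the density matrix, e.g. a
#'   closure over [pde_rhs_two_habitat()] or [pde_rhs_graph()].
#' @param n0 Initial density matrix (non-negative).
#' @param grid A [trait_grid()].
#' @param tol Steady-state tolerance on `max |dn/dt|`.
#' @param t_max Maximum integration time before giving up.
#' @param chunk Integration chunk length between residual checks.
#' @return List with the steady `n`, the [density_summary()] fields,
#'   `t_elapsed` and `residual`.
#' @export
solve_pde_steady_state <- function(rhs, n0, grid, tol = 1e-9, t_max = 5000,
                                   chunk = 25) {
  stopifnot(all(n0 >= 0))
  dm <- dim(n0)
  # integrate the smooth field; clamping inside the derivative would create
  # non-smoothness that destabilises the adaptive integrator
  deriv <- function(t, y, parms) {
    list(as.numeric(rhs(matrix(y, nrow = dm[1], ncol = dm[2]))))
  }
  n <- n0
  t_done <- 0
  repeat {
    res <- max(abs(rhs(n)))
    if (res < tol) break
    if (t_done >= t_max)
      stop(sprintf("steady state not reached by t = %g (residual %.3g)", t_max, res))
    sol <- deSolve::ode(y = as.numeric(n), times = c(0, chunk), func = deriv,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    y <- as.numeric(sol[nrow(sol), -1])
    if (min(y) < -1e-6 * max(abs(y)))
      stop("density became significantly negative: integration unstable")
    n <- matrix(pmax(y, 0), nrow = dm[1], ncol = dm[2])
    t_done <- t_done + chunk
  }
  peak <- max(n)
  if (peak > 0 && max(n[c(1, nrow(n)), ]) > 1e-8 * peak)
    warning("boundary density exceeds guard: enlarge the trait domain")
  c(list(n = n, t_elapsed = t_done, residual = res), density_summary(n, grid))
}

#' Steady state of the two-habitat reduction
#'
#' Convenience wrapper: builds the grid and initial state, integrates
#' [pde_rhs_two_habitat()] to steady state and returns the summary. Below
#' the critical migration rate the per-habitat densities are bimodal and
#' Q_ST,s is positive; above it they collapse to a single generalist peak
#' at s = 0, Q_ST,s vanishes and the per-habitat size tends to
#' bK(1 - p theta^2).
#'
#' @param params A [sim_params()] object (selection parameters are used
#'   regardless of `selection_on`).
#' @param r_theta Habitat assortativity in [-1, 1].
#' @param grid Optional [trait_grid()]; defaults to the standard grid.
#' @param ... Passed to [solve_pde_steady_state()].
#' @return As [solve_pde_steady_state()], plus `r_theta` and `grid`.
#' @export
two_habitat_steady_state <- function(params, r_theta, grid = NULL, ...) {
  if (is.null(grid)) grid <- trait_grid(params)
  n0 <- initial_density(grid, params, 2L)
  rhs <- function(n) pde_rhs_two_habitat(n, r_theta, params, grid)
  out <- solve_pde_steady_state(rhs, n0, grid, ...)
  out$r_theta <- r_theta
  out$grid <- grid
  out
}

#' Steady state of the per-vertex trait dynamics on a graph
#'
#' @param g An igraph landscape.
#' @param theta_v Per-vertex environmental optimum.
#' @param params A [sim_params()] object.
#' @param grid Optional [trait_grid()].
#' @param ... Passed to [solve_pde_steady_state()].
#' @return As [solve_pde_steady_state()], plus `grid`.
#' @export
graph_pde_steady_state <- function(g, theta_v, params, grid = NULL, ...) {
  if (is.null(grid)) grid <- trait_grid(params)
  n0 <- initial_density(grid, params, igraph::vcount(g))
  rhs <- function(n) pde_rhs_graph(n, g, theta_v, params, grid)
  out <- solve_pde_steady_state(rhs, n0, grid, ...)
  out$grid <- grid
  out
}
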