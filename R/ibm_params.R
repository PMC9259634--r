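#' Model parameters for the eco-evolutionary simulator
#'
#' Bundles and validates the constants of the individual-based model and its
#' deterministic approximations: baseline birth rate `b`, local carrying
#' capacity `K` (the death rate on a vertex holding N individuals is N/K per
#' capita), selection strength `p`, migration probability `m`, per-trait
#' mutation probability `mu`, mutation standard deviation `sigma_mu`, habitat
#' heterogeneity `theta` (the two habitat optima are -theta and +theta), and
#' the number of neutral trait components `d_neutral`. `selection_on` selects
#' between the neutral setting (constant birth rate, traits are all neutral)
#' and the heterogeneous-selection setting, where individuals additionally
#' carry an adaptive trait s with habitat-dependent birth rate
#' \eqn{b(1 - p(s - \Theta_i)^2)}.
#'
#' Defaults are the study conditions used throughout: b = 1, K = 150, p = 1,
#' mu = 0.1, sigma_mu = 0.05, theta = 0.5.
#'
#' @param b Baseline birth rate (> 0).
#' @param K Local carrying capacity (> 0).
#' @param p Selection strength (>= 0).
#' @param m Migration probability in [0, 1].
#' @param mu Per-trait mutation probability in [0, 1].
#' @param sigma_mu Mutation standard deviation (>= 0).
#' @param theta Habitat heterogeneity (>= 0).
#' @param d_neutral Number of neutral trait components (>= 1).
#' @param selection_on Logical; heterogeneous selection on or off.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(b = 1, K = 150, p = 1, m = 0.1, mu = 0.1,
                       sigma_mu = 0.05, theta = 0.5, d_neutral = 1L,
                       selection_on = FALSE) {
  stopifnot(
    b > 0, K > 0, p >= 0,
    m >= 0, m <= 1,
    mu >= 0, mu <= 1,
    sigma_mu >= 0, theta >= 0,
    d_neutral >= 1, d_neutral == round(d_neutral),
    is.logical(selection_on), length(selection_on) == 1L
  )
  structure(
    list(b = b, K = K, p = p, m = m, mu = mu, sigma_mu = sigma_mu,
         theta = theta, d_neutral = as.integer(d_neutral),
         selection_on = selection_on),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Eco-evolutionary model parameters\n")
  cat(sprintf("  b = %g, K = %g, m = %g\n", x$b, x$K, x$m))
  cat(sprintf("  mutation: mu = %g, sigma_mu = %g, d_neutral = %d\n",
              x$mu, x$sigma_mu, x$d_neutral))
  if (x$selection_on)
    cat(sprintf("  heterogeneous selection: p = %g, theta = %g\n", x$p, x$theta))
  else cat("  selection: off (neutral setting)\n")
  invisible(x)
}

#' Habitat-dependent birth rate
#'
#' Birth rate of an individual with adaptive trait `s` on a vertex with
#' environmental optimum `theta_i`: \eqn{b(1 - p(s - \Theta_i)^2)} under
#' heterogeneous selection, clamped at zero (negative rates, arising for
#' extreme maladapted mutants, are not meaningful event rates), or the
#' constant baseline `b` when selection is off.
#'
#' @param s Adaptive trait value(s); ignored when selection is off.
#' @param theta_i Environmental optimum of the vertex.
#' @param params A [sim_params()] object.
#' @return Birth rate(s), >= 0.
#' @export
birth_rate <- function(s, theta_i, params) {
  if (!params$selection_on) return(rep(params$b, length.out = max(length(s), 1L)))
  pmax(0, params$b * (1 - params$p * (s - theta_i)^2))
}

#' Per-capita death rate
#'
#' The death rate of each individual on a vertex holding `N_i` individuals is
#' `N_i / K`: competition proportional to local crowding, independent of
#' traits.
#'
#' @param N_i Local population size (>= 0).
#' @param K Local carrying capacity (> 0).
#' @return Per-capita death rate.
#' @export
death_rate <- function(N_i, K) {
  stopifnot(all(N_i >= 0), K > 0)
  N_i / K
}

#' Mutate a trait vector
#'
#' Each component is independently affected by mutation with probability
#' `mu`; a mutated component is displaced by a Normal(0, sigma_mu^2) draw
#' (continuum-of-alleles model). Uses the current R random number generator.
#'
#' @param traits Numeric vector of parental trait values.
#' @param params A [sim_params()] object.
#' @return Numeric vector of offspring trait values.
#' @export
mutate_traits <- function(traits, params) {
  hit <- stats::runif(length(traits)) < params$mu
  traits[hit] <- traits[hit] + stats::rnorm(sum(hit), 0, params$sigma_mu)
  traits
}

#' Choose the vertex an offspring settles on
#'
#' With probability `1 - m` the offspring stays on the natal vertex; with
#' probability `m` it performs one step of a simple random walk, i.e. moves
#' to a uniformly chosen neighbour. The deterministic image of this rule is
#' the migration kernel a_ij / d_j of the population-size equation.
#'
#' @param vertex Natal vertex index (1-based).
#' @param g An igraph landscape.
#' @param params A [sim_params()] object.
#' @return Vertex index of the offspring's destination.
#' @export
choose_migration_target <- function(vertex, g, params) {
  if (stats::runif(1) >= params$m) return(vertex)
  nb <- as.integer(igraph::neighbors(g, vertex))
  if (length(nb) == 0L) return(vertex)
  nb[sample.int(length(nb), 1L)]
}
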