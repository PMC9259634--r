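#' Construct a metapopulation state
#'
#' A population state holds every individual's vertex, its neutral trait
#' vector and (under selection) its adaptive trait, together with the
#' simulation clock. It is the explicit, inspectable representation used by
#' [gillespie_step()]; the production simulator [simulate_ibm()] keeps the
#' equivalent state internally.
#'
#' @param vertex Integer vector, the vertex (1-based) of each individual.
#' @param u Numeric matrix of neutral traits, one row per individual.
#' @param s Numeric vector of adaptive traits, or `NULL` when selection is
#'   off.
#' @param t Simulation time.
#' @return An object of class `population_state`.
#' @export
population_state <- function(vertex, u, s = NULL, t = 0) {
  vertex <- as.integer(vertex)
  if (!is.matrix(u)) u <- matrix(u, nrow = length(vertex))
  stopifnot(nrow(u) == length(vertex), is.null(s) || length(s) == length(vertex), t >= 0)
  structure(list(vertex = vertex, u = u, s = s, t = t), class = "population_state")
}

#' Per-vertex population sizes of a state
#'
#' @param state A [population_state()].
#' @param M Number of vertices of the landscape.
#' @return Integer vector of length `M`.
#' @export
state_counts <- function(state, M) {
  tabulate(state$vertex, nbins = M)
}

#' Initial metapopulation for the study conditions
#'
#' Places `K` individuals on every vertex (so `M * K` in total) with every
#' trait component drawn Normal(0, sigma_mu^2): a monomorphic-at-the-origin
#' founding population whose spread equals one mutation step.
#'
#' @param g An igraph landscape.
#' @param params A [sim_params()] object.
#' @return A [population_state()] at `t = 0`.
#' @export
initial_state <- function(g, params) {
  M <- igraph::vcount(g)
  n0 <- M * round(params$K)
  vertex <- rep(seq_len(M), each = round(params$K))
  u <- matrix(stats::rnorm(n0 * params$d_neutral, 0, params$sigma_mu), nrow = n0)
  s <- if (params$selection_on) stats::rnorm(n0, 0, params$sigma_mu) else NULL
  population_state(vertex, u, s)
}

#' One exact Gillespie event
#'
#' Advances the state by a single stochastic event. The waiting time is
#' Exponential with rate equal to the sum of all individual birth and death
#' rates; one event is then chosen with probability proportional to its
#' rate. A birth copies the parent, applies [mutate_traits()] to each trait
#' independently, and places the offspring with [choose_migration_target()];
#' a death removes the individual. This reference implementation is meant
#' for small states and for validating the event distribution; long runs go
#' through [simulate_ibm()].
#'
#' @param state A [population_state()].
#' @param g An igraph landscape.
#' @param theta_v Per-vertex environmental optimum (ignored when selection
#'   is off; may be `NULL` then).
#' @param params A [sim_params()] object.
#' @return The updated state, with attributes `event` (`"birth"` or
#'   `"death"`), `individual` (index the event acted on) and `extinct`.
#' @export
gillespie_step <- function(state, g, theta_v = NULL, params) {
  M <- igraph::vcount(g)
  n <- length(state$vertex)
  if (n == 0L) stop("metapopulation is extinct: total event rate is zero")
  N <- state_counts(state, M)
  theta_ind <- if (params$selection_on) theta_v[state$vertex] else rep(0, n)
  s_ind <- if (params$selection_on) state$s else rep(0, n)
  br <- birth_rate(s_ind, theta_ind, params)
  dr <- death_rate(N[state$vertex], params$K)
  total <- sum(br) + sum(dr)
  if (total <= 0) stop("total event rate is zero")
  dt <- stats::rexp(1, rate = total)
  pick <- sample.int(2L * n, 1L, prob = c(br, dr))
  state$t <- state$t + dt
  if (pick <= n) {                      # birth
    parent <- pick
    child_u <- mutate_traits(state$u[parent, ], params)
    child_s <- if (params$selection_on) mutate_traits(state$s[parent], params) else NULL
    dest <- choose_migration_target(state$vertex[parent], g, params)
    state$vertex <- c(state$vertex, dest)
    state$u <- rbind(state$u, child_u)
    if (params$selection_on) state$s <- c(state$s, child_s)
    attr(state, "event") <- "birth"
    attr(state, "individual") <- parent
  } else {                              # death
    victim <- pick - n
    state$vertex <- state$vertex[-victim]
    state$u <- state$u[-victim, , drop = FALSE]
    if (params$selection_on) state$s <- state$s[-victim]
    attr(state, "event") <- "death"
    attr(state, "individual") <- victim
  }
  attr(state, "extinct") <- length(state$vertex) == 0L
  state
}
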