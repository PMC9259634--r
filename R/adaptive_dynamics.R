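#' Two-habitat projection matrix
#'
#' The linear growth operator of a rare type with adaptive trait `s` in the
#' two-habitat reduction (mutation omitted, trait-substitution regime):
#' diagonal entries are the local net growth rates
#' \eqn{\mathfrak r^h(s, \bar N^h) = b^h(s)(1 + \tfrac{m}{2}(r_\Theta - 1)) - \bar N^h/K}
#' and off-diagonal entries are the cross-habitat migrant fluxes
#' \eqn{\tfrac{m}{2}(1 - r_\Theta) b^{h'}(s)}.
#'
#' @param s Trait value of the (rare) type.
#' @param N_res Length-2 vector of resident population sizes per habitat.
#' @param params A [sim_params()] object (`b`, `K`, `p`, `m`, `theta`).
#' @param r_theta Habitat assortativity in [-1, 1].
#' @return A 2x2 numeric matrix.
#' @export
projection_matrix <- function(s, N_res, params, r_theta) {
  stopifnot(length(N_res) == 2L)
  bI <- params$b * (1 - params$p * (s + params$theta)^2)   # optimum -theta
  bII <- params$b * (1 - params$p * (s - params$theta)^2)  # optimum +theta
  cm <- (params$m / 2) * (1 - r_theta)
  matrix(c(
    bI * (1 - cm) - N_res[1] / params$K, cm * bI,
    cm * bII, bII * (1 - cm) - N_res[2] / params$K
  ), nrow = 2, byrow = FALSE)
}

#' Invasion fitness of a rare mutant
#'
#' The fitness of a rare type with trait `y` in a resident population at
#' sizes `N_res` is the leading eigenvalue of the [projection_matrix()],
#' computed in closed form for the 2x2 case. At the resident's demographic
#' equilibrium the resident's own fitness is zero.
#'
#' @param y Mutant trait value.
#' @param N_res Length-2 vector of per-habitat resident sizes.
#' @param params A [sim_params()] object.
#' @param r_theta Habitat assortativity.
#' @return Leading eigenvalue (real part when the pair is complex, which
#'   only happens when both birth rates are negative, far outside the
#'   viable trait range).
#' @export
invasion_fitness <- function(y, N_res, params, r_theta) {
  Mx <- projection_matrix(y, N_res, params, r_theta)
  tr <- Mx[1, 1] + Mx[2, 2]
  disc <- (Mx[1, 1] - Mx[2, 2])^2 + 4 * Mx[1, 2] * Mx[2, 1]
  if (disc < 0) return(tr / 2)
  (tr + sqrt(disc)) / 2
}

#' Critical migration rate for local adaptation
#'
#' Above the threshold
#' \deqn{m^\star = \frac{1}{1 - r_\Theta}\,\frac{4 p \theta^2}{1 + 3 p \theta^2}}
#' the generalist strategy s* = 0 is evolutionarily stable and local
#' adaptation (and with it adaptive differentiation) is lost; below it the
#' generalist can be invaded and specialists coexist. The threshold grows
#' with selection strength, habitat heterogeneity and habitat
#' assortativity; at r_theta = 1 the habitats decouple and adaptation is
#' never lost (infinite threshold, returned as `Inf` with a message
#' attribute).
#'
#' @param p Selection strength (> 0).
#' @param theta Habitat heterogeneity (> 0).
#' @param r_theta Habitat assortativity in [-1, 1].
#' @return The critical migration rate (may exceed 1, in which case no
#'   admissible migration probability destroys adaptation).
#' @export
critical_migration <- function(p, theta, r_theta) {
  stopifnot(p > 0, theta > 0, r_theta >= -1, r_theta <= 1)
  if (r_theta == 1) {
    out <- Inf
    attr(out, "note") <- "assortativity 1: habitats decouple, adaptation never lost"
    return(out)
  }
  (1 / (1 - r_theta)) * 4 * p * theta^2 / (1 + 3 * p * theta^2)
}

#' Singular strategy of the two-habitat model
#'
#' Locates the trait value where the fitness gradient of a rare mutant
#' vanishes. For symmetric habitats (optima -theta and +theta) the singular
#' strategy is the habitat midpoint s* = 0 and the associated demographic
#' equilibrium is \eqn{\bar N^{I} = \bar N^{II} = bK(1 - p\theta^2)}; the
#' gradient root is nevertheless found numerically (central differences +
#' root bracketing) as a consistency check.
#'
#' @param params A [sim_params()] object.
#' @param r_theta Habitat assortativity.
#' @param tol Root-finding tolerance on s*.
#' @return List with `s_star`, `N_star` (per-habitat equilibrium sizes),
#'   `m_star` (critical migration rate), `stable` (logical, `NA` when
#'   marginal) and `curvature` (second derivative of mutant fitness at s*).
#' @export
singular_strategy <- function(params, r_theta, tol = 1e-10) {
  N_star <- rep(params$b * params$K * (1 - params$p * params$theta^2), 2L)
  grad <- function(y) fitness_deriv(y, N_star, params, r_theta, order = 1L)
  hw <- max(params$theta / 2, 1e-3)
  if (grad(-hw) * grad(hw) > 0) stop("fitness gradient root not bracketed")
  s_star <- stats::uniroot(grad, c(-hw, hw), tol = tol)$root
  es <- evolutionary_stability(s_star, params, r_theta)
  list(s_star = s_star, N_star = N_star,
       m_star = critical_migration(params$p, params$theta, r_theta),
       stable = es$stable, curvature = es$curvature)
}

# central finite differences of the invasion fitness in the mutant trait
fitness_deriv <- function(y, N_res, params, r_theta, order = 1L, h = 1e-5) {
  f <- function(z) invasion_fitness(z, N_res, params, r_theta)
  if (order == 1L) (f(y + h) - f(y - h)) / (2 * h)
  else (f(y + h) - 2 * f(y) + f(y - h)) / h^2
}

#' Evolutionary stability of a singular strategy
#'
#' Evaluates the curvature of mutant fitness at the singular strategy with
#' the resident at its demographic equilibrium. Negative curvature means
#' the strategy is a fitness maximum (evolutionarily stable: a single
#' generalist persists); positive curvature means it is invasible
#' (disruptive selection: specialist branching). Curvature within a small
#' band of zero is reported as marginal (`stable = NA`).
#'
#' @param s_star Singular trait value (0 for symmetric habitats).
#' @param params A [sim_params()] object.
#' @param r_theta Habitat assortativity.
#' @param marginal_tol Half-width of the inconclusive curvature band.
#' @return List with `stable` (`TRUE`/`FALSE`/`NA`) and `curvature`.
#' @export
evolutionary_stability <- function(s_star, params, r_theta, marginal_tol = 1e-8) {
  N_star <- rep(params$b * params$K * (1 - params$p * params$theta^2), 2L)
  curv <- fitness_deriv(s_star, N_star, params, r_theta, order = 2L)
  stable <- if (abs(curv) < marginal_tol) NA else curv < 0
  list(stable = stable, curvature = curv)
}

#' Numerically locate the stability threshold in migration
#'
#' Finds the migration rate at which the fitness curvature at the singular
#' strategy changes sign, by root bracketing on m. This is an independent
#' numerical route to the critical migration rate: it evaluates the
#' eigenvalue curvature directly and never uses the closed-form threshold
#' of [critical_migration()], against which it can therefore be validated.
#'
#' @param params A [sim_params()] object (its `m` is ignored).
#' @param r_theta Habitat assortativity (< 1).
#' @param interval Search interval for m.
#' @param tol Root tolerance.
#' @return The migration rate at the first curvature sign change (disruptive
#'   at smaller m, stabilising beyond). When the generalist is demographically
#'   inviable (`p theta^2 > 1`) the curvature can change sign again at much
#'   larger m; the first crossing is the adaptation threshold.
#' @export
stability_threshold <- function(params, r_theta, interval = c(1e-6, 100), tol = 1e-12) {
  curv_at <- function(m) {
    pp <- params
    pp$m <- m
    evolutionary_stability(0, pp, r_theta, marginal_tol = 0)$curvature
  }
  grid_m <- exp(seq(log(interval[1]), log(interval[2]), length.out = 256L))
  cv <- vapply(grid_m, curv_at, numeric(1))
  flip <- which(cv[-1] * cv[-length(cv)] <= 0)
  if (!length(flip)) stop("curvature does not change sign on the interval")
  stats::uniroot(curv_at, grid_m[c(flip[1], flip[1] + 1L)], tol = tol)$root
}
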