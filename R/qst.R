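#' Quantitative-trait differentiation Q_ST
#'
#' Computes \eqn{Q_{ST} = \sigma^2_B / (\sigma^2_B + \sigma^2_W)} for one
#' trait dimension sampled over the vertices of a landscape.
#' \eqn{\sigma^2_B} is the variance of the per-vertex trait means around
#' their unweighted grand mean, and \eqn{\sigma^2_W} is the average
#' within-vertex trait variance. All variances are population variances
#' (divide by n), matching the expectation-form definition for haploid
#' populations. Vertices without individuals (local extinction) are
#' excluded from both components: the statistic conditions on resident
#' individuals.
#'
#' @param sample A list with one numeric vector of trait values per vertex,
#'   or a two-column data frame / matrix of `(vertex, value)` pairs.
#' @return Q_ST in [0, 1]; `NA` (with a warning) when all values are
#'   identical, where the ratio is 0/0.
#' @examples
#' qst(list(c(0, 2), c(1, 3)))  # 0.25 / (0.25 + 1) = 0.2
#' @export
qst <- function(sample) {
  sample <- as_trait_sample(sample)
  sample <- sample[lengths(sample) > 0L]
  if (length(sample) < 2L)
    stop("Q_ST needs at least two vertices with at least one individual each")
  vbar <- vapply(sample, mean, numeric(1))
  sigma2_B <- mean((vbar - mean(vbar))^2)
  sigma2_W <- mean(vapply(sample, pop_var, numeric(1)))
  if (sigma2_B + sigma2_W == 0) {
    warning("all trait values identical: Q_ST undefined (0/0)")
    return(NA_real_)
  }
  sigma2_B / (sigma2_B + sigma2_W)
}

pop_var <- function(x) mean((x - mean(x))^2)

as_trait_sample <- function(sample) {
  if (is.data.frame(sample) || (is.matrix(sample) && ncol(sample) == 2L)) {
    sample <- as.data.frame(sample)
    return(split(sample[[2]], sample[[1]]))
  }
  if (!is.list(sample)) stop("'sample' must be a list of per-vertex trait vectors")
  lapply(sample, as.numeric)
}

#' Mean Q_ST over independent trait dimensions
#'
#' Averaging over many independently mutating neutral traits reduces the
#' large quadratic variation of single-trait Q_ST: the variance of the mean
#' scales as 1/d for d independent traits.
#'
#' @param samples A list of trait samples (one per trait dimension), each as
#'   accepted by [qst()].
#' @return The arithmetic mean of the per-trait Q_ST values; per-trait
#'   undefined values are excluded with a warning reporting how many.
#' @export
qst_mean <- function(samples) {
  vals <- vapply(samples, function(s) {
    tryCatch(suppressWarnings(qst(s)), error = function(e) NA_real_)
  }, numeric(1))
  n_bad <- sum(is.na(vals))
  if (n_bad > 0L)
    warning(sprintf("%d of %d per-trait Q_ST values undefined; excluded from the mean",
                    n_bad, length(vals)))
  mean(vals, na.rm = TRUE)
}

# Q_ST from per-vertex sufficient statistics (means + population variances),
# excluding vertices with n = 0. Used on recorded trajectory summaries.
qst_from_moments <- function(n, means, vars) {
  keep <- n > 0 & !is.na(means)
  if (sum(keep) < 2L) return(NA_real_)
  vbar <- means[keep]
  sigma2_B <- mean((vbar - mean(vbar))^2)
  sigma2_W <- mean(vars[keep])
  if (sigma2_B + sigma2_W == 0) return(NA_real_)
  sigma2_B / (sigma2_B + sigma2_W)
}

#' Per-record differentiation series of a trajectory
#'
#' Computes, for every recorded time of an [simulate_ibm()] trajectory, the
#' neutral differentiation Q_ST,u (averaged over the neutral trait
#' dimensions), the adaptive differentiation Q_ST,s (when selection is on)
#' and the mean per-vertex population size.
#'
#' @param traj An `ibm_trajectory`.
#' @param rows Optional integer vector restricting the computation to a
#'   subset of record indices (used by [time_averaged_summary()]).
#' @return Data frame with columns `t`, `qst_u`, `qst_s` (NA without
#'   selection) and `N_bar`.
#' @export
trajectory_qst <- function(traj, rows = NULL) {
  stopifnot(inherits(traj, "ibm_trajectory"))
  R <- nrow(traj$N)
  if (is.null(rows)) rows <- seq_len(R)
  d <- dim(traj$u_mean)[3]
  qst_u <- qst_s <- rep(NA_real_, R)
  for (r in rows) {
    n <- traj$N[r, ]
    if (all(is.na(n))) next
    per_trait <- vapply(seq_len(d), function(j)
      qst_from_moments(n, traj$u_mean[r, , j], traj$u_var[r, , j]), numeric(1))
    qst_u[r] <- mean(per_trait, na.rm = TRUE)
    if (!is.null(traj$s_mean))
      qst_s[r] <- qst_from_moments(n, traj$s_mean[r, ], traj$s_var[r, ])
  }
  out <- data.frame(t = traj$time, qst_u = qst_u, qst_s = qst_s,
                    N_bar = rowMeans(traj$N))
  out[rows, , drop = FALSE]
}

#' Time-averaged summary of a trajectory
#'
#' Averages the differentiation statistics and mean population size over the
#' recorded states in the closing window `[t_end - window, t_end]`,
#' discarding the transient. `window = 0` keeps only the last recorded
#' state. The default window used by the ensemble experiments is the last
#' 10\% of the time span.
#'
#' @param traj An `ibm_trajectory`.
#' @param window Width of the closing averaging window (model time units).
#' @return A one-row data frame with `qst_u`, `qst_s`, `N_bar`,
#'   `n_records` and `extinct`. Extinct trajectories yield NA statistics
#'   and `extinct = TRUE`.
#' @export
time_averaged_summary <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "ibm_trajectory"))
  t_end <- traj$time[length(traj$time)]
  if (is.null(window)) window <- 0.1 * t_end
  stopifnot(window >= 0, window <= t_end)
  if (traj$extinct) {
    return(data.frame(qst_u = NA_real_, qst_s = NA_real_, N_bar = NA_real_,
                      n_records = 0L, extinct = TRUE))
  }
  rows <- which(traj$time >= t_end - window - 1e-9)
  s <- trajectory_qst(traj, rows = rows)
  data.frame(
    qst_u = mean(s$qst_u, na.rm = TRUE),
    qst_s = if (all(is.na(s$qst_s))) NA_real_ else mean(s$qst_s, na.rm = TRUE),
    N_bar = mean(s$N_bar),
    n_records = nrow(s),
    extinct = FALSE
  )
}
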