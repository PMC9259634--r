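#' Configuration of an ensemble experiment
#'
#' Bundles everything a reproducible simulation campaign needs: the model
#' setting, the graph ensemble size, the migration values, replication, the
#' time span and averaging window, and the master seed from which every
#' per-run seed is derived deterministically.
#'
#' The default campaign is sized for a desk machine: 60 graphs stratified
#' by edge count from the M = 7 ensemble, 3 habitat labelings per graph
#' (selection setting), 3 replicates, `t_end = 300` with the last 10% as
#' averaging window, and 30 neutral trait dimensions. The full published
#' campaign scale (all 853 graphs, 5 replicates, t = 1000, 300 neutral
#' traits) is reached by overriding these fields and is a cluster-sized
#' computation.
#'
#' @param setting `"neutral"` (no selection) or `"selection"`.
#' @param M Vertex count of the graph ensemble.
#' @param m_values Migration probabilities to sweep.
#' @param n_graphs Graphs retained from the ensemble by stratified
#'   edge-count sampling (`Inf` keeps all).
#' @param labelings_per_graph Two-type habitat labelings per graph
#'   (selection setting), spread across assortativity quartiles.
#' @param replicates IBM replicates per (graph, labeling, m).
#' @param t_end Time span of each run.
#' @param window Averaging window; default last 10% of `t_end`.
#' @param d_neutral Neutral trait dimensions.
#' @param params Base [sim_params()]; `m`, `d_neutral` and `selection_on`
#'   are overridden per run.
#' @param seed Master integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(setting = c("neutral", "selection"),
                              M = 7L,
                              m_values = if (setting[1] == "neutral") c(0.01, 0.5) else c(0.05, 0.5),
                              n_graphs = 60L,
                              labelings_per_graph = 3L,
                              replicates = 3L,
                              t_end = 300,
                              window = NULL,
                              d_neutral = 30L,
                              params = sim_params(),
                              seed = 1L) {
  setting <- match.arg(setting)
  if (is.null(window)) window <- 0.1 * t_end
  stopifnot(replicates >= 1L, t_end > 0, all(m_values >= 0 & m_values <= 1),
            length(seed) == 1L)
  structure(list(
    setting = setting, M = as.integer(M), m_values = m_values,
    n_graphs = n_graphs, labelings_per_graph = as.integer(labelings_per_graph),
    replicates = as.integer(replicates), t_end = t_end, window = window,
    d_neutral = as.integer(d_neutral), params = params, seed = as.integer(seed)
  ), class = "experiment_config")
}

# deterministic per-run seed derived from the master seed (kept < 2^31)
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (i in idx) s <- (s * 69069 + i * 2654435761) %% 2147483647
  as.integer(max(s, 1))
}

config_graphs <- function(config) {
  graphs <- enumerate_connected_graphs(config$M)
  if (is.finite(config$n_graphs) && config$n_graphs < length(graphs)) {
    per <- max(1L, ceiling(config$n_graphs / length(unique(
      vapply(graphs, function(g) as.integer(igraph::ecount(g)), integer(1))))))
    graphs <- stratified_graph_sample(graphs, per, seed = derive_seed(config$seed, 1L))
    if (length(graphs) > config$n_graphs) {
      keep <- with_seed(derive_seed(config$seed, 2L),
                        sort(sample.int(length(graphs), config$n_graphs)))
      graphs <- graphs[keep]
    }
  }
  graphs
}

run_params <- function(config, m) {
  p <- config$params
  p$m <- m
  p$d_neutral <- config$d_neutral
  p$selection_on <- config$setting == "selection"
  p
}

#' Run the no-selection ensemble campaign
#'
#' For every graph in the (possibly stratified) ensemble and every
#' migration value, simulates IBM replicates without selection, summarises
#' each run over the closing window, averages over replicates, attaches the
#' landscape metrics, and fits the standardized regression of neutral
#' differentiation on average path length and degree homogeneity
#' independently per migration value.
#'
#' @param config An [experiment_config()] with `setting = "neutral"`.
#' @param progress Print a line per graph.
#' @return List of class `ensemble_result` with `runs` (per-replicate
#'   rows), `table` (replicate-averaged rows), `regressions` (one
#'   [standardized_regression()] per m, univariate and multivariate) and
#'   `config`.
#' @export
run_neutral_ensemble <- function(config, progress = FALSE) {
  stopifnot(config$setting == "neutral")
  graphs <- config_graphs(config)
  metrics <- graph_metrics_table(graphs)
  runs <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (progress) message(sprintf("graph %d/%d", gi, length(graphs)))
    for (m in config$m_values) {
      pars <- run_params(config, m)
      for (rep in seq_len(config$replicates)) {
        sd <- derive_seed(config$seed, gi, round(1e6 * m), rep)
        traj <- simulate_ibm(g, pars, t_end = config$t_end, seed = sd)
        sm <- time_averaged_summary(traj, config$window)
        runs[[length(runs) + 1L]] <- cbind(
          metrics[gi, c("graph_id", "M", "edges", "mean_path_length", "h_d")],
          data.frame(m = m, replicate = rep, seed = sd), sm)
      }
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  tab <- stats::aggregate(cbind(qst_u, N_bar) ~ graph_id + m + mean_path_length + h_d + edges,
                          data = runs, FUN = mean, na.action = stats::na.omit)
  regressions <- lapply(stats::setNames(config$m_values, paste0("m_", config$m_values)),
    function(m) {
      sub <- tab[tab$m == m, ]
      list(
        univariate_l = fit_or_null(sub, "mean_path_length", "qst_u"),
        univariate_hd = fit_or_null(sub, "h_d", "qst_u"),
        multivariate = fit_or_null(sub, c("mean_path_length", "h_d"), "qst_u")
      )
    })
  structure(list(runs = runs, table = tab, regressions = regressions,
                 config = config), class = "ensemble_result")
}

#' Run the heterogeneous-selection ensemble campaign
#'
#' As [run_neutral_ensemble()], with habitat labelings sampled per graph
#' across assortativity quartiles and selection switched on. Records both
#' adaptive (Q_ST,s) and neutral (Q_ST,u) differentiation and fits the
#' standardized regressions of each on average path length, degree
#' homogeneity and habitat assortativity per migration value.
#'
#' @param config An [experiment_config()] with `setting = "selection"`.
#' @param progress Print a line per graph.
#' @return List of class `ensemble_result`; `table` carries `r_theta`,
#'   `qst_s`, `qst_u`, `N_bar`, and `regressions` has elements `qst_s` and
#'   `qst_u` per migration value.
#' @export
run_selection_ensemble <- function(config, progress = FALSE) {
  stopifnot(config$setting == "selection")
  graphs <- config_graphs(config)
  metrics <- graph_metrics_table(graphs)
  runs <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (progress) message(sprintf("graph %d/%d", gi, length(graphs)))
    labs <- spread_labelings(g, config)
    for (li in seq_along(labs)) {
      theta_v <- labs[[li]]
      r_th <- attr(theta_v, "r_theta")
      for (m in config$m_values) {
        pars <- run_params(config, m)
        for (rep in seq_len(config$replicates)) {
          sd <- derive_seed(config$seed, gi, li, round(1e6 * m), rep)
          traj <- simulate_ibm(g, pars, theta_v = theta_v,
                               t_end = config$t_end, seed = sd)
          sm <- time_averaged_summary(traj, config$window)
          runs[[length(runs) + 1L]] <- cbind(
            metrics[gi, c("graph_id", "M", "edges", "mean_path_length", "h_d")],
            data.frame(labeling_id = li, r_theta = r_th, m = m,
                       replicate = rep, seed = sd), sm)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  tab <- stats::aggregate(
    cbind(qst_u, qst_s, N_bar) ~ graph_id + labeling_id + m +
      mean_path_length + h_d + r_theta + edges,
    data = runs, FUN = mean, na.action = stats::na.omit)
  preds <- c("mean_path_length", "h_d", "r_theta")
  regressions <- lapply(stats::setNames(config$m_values, paste0("m_", config$m_values)),
    function(m) {
      sub <- tab[tab$m == m, ]
      list(qst_s = fit_or_null(sub, preds, "qst_s"),
           qst_u = fit_or_null(sub, preds, "qst_u"))
    })
  structure(list(runs = runs, table = tab, regressions = regressions,
                 config = config), class = "ensemble_result")
}

# meta-analysis regressions need enough rows to be meaningful; smoke-sized
# campaigns simply skip them
fit_or_null <- function(tab, predictors, response, min_rows = 10L) {
  if (nrow(tab) < max(min_rows, length(predictors) + 2L)) return(NULL)
  tryCatch(standardized_regression(tab, predictors, response),
           error = function(e) {
             warning("regression skipped: ", conditionMessage(e))
             NULL
           })
}

# labelings spread across assortativity quartiles, capped per graph
spread_labelings <- function(g, config) {
  labs <- sample_habitat_assignments(
    g, theta = config$params$theta,
    n_per_stratum = max(1L, ceiling(config$labelings_per_graph / 4)),
    seed = derive_seed(config$seed, 3L, igraph::ecount(g),
                       sum(igraph::degree(g)^2)))
  if (length(labs) > config$labelings_per_graph) {
    r <- vapply(labs, attr, numeric(1), "r_theta")
    keep <- unique(round(seq(1, length(labs), length.out = config$labelings_per_graph)))
    labs <- labs[order(r)][keep]
  }
  labs
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble campaign (%s setting): %d rows over %d graphs, m in {%s}\n",
              x$config$setting, nrow(x$table),
              length(unique(x$table$graph_id)),
              paste(x$config$m_values, collapse = ", ")))
  for (nm in names(x$regressions)) {
    cat("--", nm, "--\n")
    regs <- x$regressions[[nm]]
    if (inherits(regs, "std_regression")) print(regs) else
      for (r in regs) if (!is.null(r)) print(r)
  }
  invisible(x)
}

#' Compare IBM simulations with the two-habitat mean-field prediction
#'
#' For each (graph, labeling, migration) combination, runs IBM replicates
#' under heterogeneous selection and solves the two-habitat reduction at
#' the labeling's assortativity, then tabulates the mean population size
#' and adaptive differentiation from both routes. The reduction is expected
#' to track the simulations closely at low migration; at high migration the
#' stochastic simulations retain extra differentiation driven by drift.
#'
#' @param config An [experiment_config()] with `setting = "selection"`.
#' @param graphs Optional list of graphs (default: the config ensemble).
#' @param progress Print a line per graph.
#' @return Data frame with one row per (graph, labeling, m): IBM and PDE
#'   `N_bar` and `qst_s`, and their differences.
#' @export
compare_ibm_pde <- function(config, graphs = NULL, progress = FALSE) {
  stopifnot(config$setting == "selection")
  if (is.null(graphs)) graphs <- config_graphs(config)
  grid <- trait_grid(config$params)
  pde_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (progress) message(sprintf("graph %d/%d", gi, length(graphs)))
    labs <- spread_labelings(g, config)
    for (li in seq_along(labs)) {
      theta_v <- labs[[li]]
      r_th <- attr(theta_v, "r_theta")
      for (m in config$m_values) {
        pars <- run_params(config, m)
        sums <- lapply(seq_len(config$replicates), function(rep) {
          sd <- derive_seed(config$seed, 7L, gi, li, round(1e6 * m), rep)
          time_averaged_summary(
            simulate_ibm(g, pars, theta_v = theta_v, t_end = config$t_end, seed = sd),
            config$window)
        })
        ibm_N <- mean(vapply(sums, `[[`, numeric(1), "N_bar"))
        ibm_q <- mean(vapply(sums, `[[`, numeric(1), "qst_s"))
        key <- sprintf("%.6f_%.6f", r_th, m)
        if (is.null(pde_cache[[key]]))
          pde_cache[[key]] <- two_habitat_steady_state(pars, r_th, grid = grid,
                                                       tol = 1e-8)
        pde <- pde_cache[[key]]
        rows[[length(rows) + 1L]] <- data.frame(
          graph_id = igraph::graph_attr(g, "name") %||% paste0("graph_", gi),
          labeling_id = li, m = m, r_theta = r_th,
          ibm_N_bar = ibm_N, pde_N_bar = pde$N_bar,
          ibm_qst_s = ibm_q, pde_qst_s = pde$qst_s,
          dN = ibm_N - pde$N_bar, dqst = ibm_q - pde$qst_s)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ensemble outputs to a directory
#'
#' Writes the replicate-level and averaged tables as CSV, the regression
#' reports as JSON, the graphs as edge-list files and (selection setting)
#' the labelings as CSV, so that every row's metrics can be recomputed from
#' the stored inputs.
#'
#' @param result An `ensemble_result`.
#' @param dir Output directory (created if missing).
#' @param graphs Optional list of the graphs used (stored when given).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(result, dir, graphs = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(result$table, file.path(dir, "results.csv"), row.names = FALSE)
  reg <- lapply(result$regressions, function(regs) {
    if (inherits(regs, "std_regression")) regs <- list(model = regs)
    regs <- Filter(Negate(is.null), regs)
    lapply(regs, function(r) list(
      response = r$response, coefficients = r$coefficients,
      r_squared = r$r_squared, n = r$n, condition_number = r$condition_number))
  })
  jsonlite::write_json(reg, file.path(dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(graphs)) {
    gdir <- file.path(dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    for (i in seq_along(graphs))
      write_edgelist(graphs[[i]],
                     file.path(gdir, sprintf("%s.txt",
                       igraph::graph_attr(graphs[[i]], "name") %||% paste0("graph_", i))))
  }
  invisible(dir)
}
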