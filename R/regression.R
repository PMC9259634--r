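#' Standardized multivariate regression of differentiation on graph metrics
#'
#' Ordinary least squares of a response on z-scored predictors (and z-scored
#' response), as used in the ensemble meta-analysis relating Q_ST to the
#' landscape metrics. Standardized coefficients make the effects of
#' predictors with different units comparable; 95% confidence intervals and
#' R-squared are reported. Collinearity is surfaced through the condition
#' number of the standardized design matrix rather than by silently
#' dropping predictors.
#'
#' @param table Data frame of ensemble results.
#' @param predictors Character vector of predictor column names.
#' @param response Name of the response column.
#' @return An object of class `std_regression`: list with `coefficients`
#'   (data frame of estimate, CI bounds, p value per predictor),
#'   `r_squared`, `n`, `condition_number`, `response` and the fitted `lm`
#'   object.
#' @export
standardized_regression <- function(table, predictors, response) {
  stopifnot(is.data.frame(table), all(c(predictors, response) %in% names(table)))
  df <- table[stats::complete.cases(table[c(predictors, response)]),
              c(predictors, response), drop = FALSE]
  if (nrow(df) < length(predictors) + 2L)
    stop("too few complete rows for the regression")
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds[predictors] == 0))
    stop("predictor(s) with zero variance: ",
         paste(predictors[sds[predictors] == 0], collapse = ", "))
  z <- as.data.frame(scale(df))
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = z)
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)
  coefs <- data.frame(
    term = predictors,
    estimate = stats::coef(fit)[predictors],
    ci_lower = ci[predictors, 1],
    ci_upper = ci[predictors, 2],
    p_value = sm$coefficients[predictors, 4],
    row.names = NULL
  )
  X <- stats::model.matrix(fit)[, predictors, drop = FALSE]
  structure(list(
    coefficients = coefs,
    r_squared = sm$r.squared,
    n = nrow(df),
    condition_number = kappa(X, exact = TRUE),
    response = response,
    fit = fit
  ), class = "std_regression")
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s ~ %s   (n = %d, R^2 = %.3f)\n",
              x$response, paste(x$coefficients$term, collapse = " + "),
              x$n, x$r_squared))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  if (x$condition_number > 30)
    cat(sprintf("  warning: design condition number %.1f suggests collinearity\n",
                x$condition_number))
  invisible(x)
}

#' Export a regression report as JSON
#'
#' @param x A `std_regression` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(x, path) {
  stopifnot(inherits(x, "std_regression"))
  jsonlite::write_json(list(
    response = x$response,
    coefficients = x$coefficients,
    r_squared = x$r_squared,
    n = x$n,
    condition_number = x$condition_number
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
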