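#' Validate an observation table
#'
#' The fitting functions consume "observation tables": one row per
#' observation with columns `tree_id`, `species`, `d0_mm` (stem-base
#' diameter, mm), `response` (the measured value) and, for the two-predictor
#' power models, `hg_cm` (height above ground, cm). A `response_kind` column
#' (`"height_m"`, `"dbh_mm"`, `"thickness_mm"` or `"radius_cm"`) identifies
#' the measurement; each fitter requires a single kind.
#'
#' @param data A data frame of observations.
#' @param response_kind The expected kind; if the table has a
#'   `response_kind` column it must match.
#' @return `data` as a tibble, invisibly validated.
#' @export
validate_observations <- function(data,
                                  response_kind = c("height_m", "dbh_mm",
                                                    "thickness_mm", "radius_cm")) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  needed <- c("d0_mm", "response")
  two_pred <- response_kind %in% c("thickness_mm", "radius_cm")
  if (two_pred) needed <- c(needed, "hg_cm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("observation table for %s lacks column(s): %s",
                  response_kind, paste(missing_cols, collapse = ", ")))
  }
  if ("response_kind" %in% names(data)) {
    kinds <- unique(data$response_kind)
    if (!identical(kinds, response_kind)) {
      abort(sprintf("expected response_kind '%s' but table holds: %s",
                    response_kind, paste(kinds, collapse = ", ")))
    }
  }
  if (anyNA(data[needed])) abort("observation table contains missing values")
  if (any(data$d0_mm <= 0)) abort("d0_mm must be positive")
  data
}

.new_allo_fit <- function(model_form, response_kind, fit, data, n_params) {
  sm <- summary(fit)
  cf <- sm$coefficients
  observed <- data$response
  predicted <- as.numeric(fitted(fit))
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  n <- length(observed)
  conv <- fit$convInfo
  structure(
    list(
      model_form = model_form,
      response_kind = response_kind,
      coefficients = tibble::tibble(
        term = rownames(cf),
        estimate = unname(cf[, "Estimate"]),
        std.error = unname(cf[, "Std. Error"]),
        statistic = unname(cf[, "t value"]),
        p.value = unname(cf[, grep("^Pr", colnames(cf))])
      ),
      stats = list(
        r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
        mse = sse / (n - n_params),
        sse = sse,
        n = n,
        df_residual = n - n_params
      ),
      convergence = list(
        converged = is.null(conv) || isTRUE(conv$isConv),
        iterations = if (!is.null(conv)) conv$finIter else NA_integer_,
        final_tol = if (!is.null(conv)) conv$finTol else NA_real_
      ),
      fit = fit,
      data = data
    ),
    class = "allo_fit"
  )
}

#' Fit the linear DBH-on-D0 model
#'
#' Ordinary least squares for `DBH = b0 + b1 * D0` (both mm). Standard
#' errors and two-sided p-values come from the usual t statistics on
#' `n - 2` residual degrees of freedom; `mse = SSE / (n - 2)`.
#'
#' @param data An observation table (see [validate_observations()]) with
#'   `response_kind = "dbh_mm"`.
#' @return An object of class `"allo_fit"`; see [tidy.allo_fit()] and
#'   [glance.allo_fit()].
#' @export
fit_dbh_linear <- function(data) {
  data <- validate_observations(data, "dbh_mm")
  if (nrow(data) < 3L) abort("need at least 3 observations to fit the DBH line")
  if (length(unique(data$d0_mm)) < 2L) abort("d0_mm values are all identical: rank-deficient design")
  fit <- lm(response ~ d0_mm, data = data)
  fit$call <- quote(lm(response ~ d0_mm))
  out <- .new_allo_fit("linear_dbh", "dbh_mm", fit, data, n_params = 2L)
  out$coefficients$term <- c("b0", "b1")
  out
}

#' Fit the rational height model
#'
#' Nonlinear least squares on the original scale for
#' `H = D0^2 / (b0 + b1 D0 + b2 D0^2)` (height in m, `D0` in mm), using a
#' Levenberg--Marquardt optimiser started from the exact linearisation
#' (OLS of `D0^2 / H` on `1, D0, D0^2`). Standard errors are asymptotic
#' (Jacobian-based) with `n - 3` residual degrees of freedom.
#'
#' @param data An observation table with `response_kind = "height_m"`.
#' @return An `"allo_fit"` object.
#' @export
fit_height_rational <- function(data) {
  data <- validate_observations(data, "height_m")
  if (nrow(data) < 4L) abort("need at least 4 observations to fit the height model")
  if (length(unique(data$d0_mm)) < 2L) abort("d0_mm values are all identical")
  if (any(data$response <= 0)) abort("heights must be positive")
  # linearised start: d0^2 / H is quadratic in d0 with the same coefficients
  z <- data$d0_mm^2 / data$response
  init <- coef(lm(z ~ data$d0_mm + I(data$d0_mm^2)))
  start <- list(b0 = unname(init[1]), b1 = unname(init[2]), b2 = unname(init[3]))
  fit <- .nls_lm(response ~ d0_mm^2 / (b0 + b1 * d0_mm + b2 * d0_mm^2),
                 data = data, start = start)
  .new_allo_fit("rational_height", "height_m", fit, data, n_params = 3L)
}

#' Fit a two-predictor power model
#'
#' Nonlinear least squares on the original scale for
#' `y = b0 * D0^b1 * Hg^b2`, the shared form of the bark-thickness model
#' (response in mm) and the stem-radius model (response in cm). The
#' optimiser is initialised from a log--log OLS fit, which solves the
#' multiplicative-error version of the same model; the reported estimates,
#' standard errors, R^2 and `mse = SSE / (n - 3)` all refer to the
#' original-scale (additive-error) criterion.
#'
#' @param data An observation table with `response_kind` `"thickness_mm"` or
#'   `"radius_cm"`; all responses and predictors must be positive.
#' @param response_kind Which of the two power-model responses the table holds.
#' @return An `"allo_fit"` object.
#' @export
fit_power_model <- function(data, response_kind = c("thickness_mm", "radius_cm")) {
  response_kind <- match.arg(response_kind)
  data <- validate_observations(data, response_kind)
  if (nrow(data) < 5L) abort("need at least 5 observations to fit the power model")
  if (length(unique(data$d0_mm)) < 2L || length(unique(data$hg_cm)) < 2L) {
    abort("both d0_mm and hg_cm must vary")
  }
  if (any(data$response <= 0)) abort("power-model responses must be positive")
  if (any(data$hg_cm <= 0)) abort("hg_cm must be positive")
  init <- coef(lm(log(response) ~ log(d0_mm) + log(hg_cm), data = data))
  start <- list(b0 = exp(unname(init[1])), b1 = unname(init[2]), b2 = unname(init[3]))
  fit <- .nls_lm(response ~ b0 * d0_mm^b1 * hg_cm^b2, data = data, start = start)
  .new_allo_fit("power_two_predictor", response_kind, fit, data, n_params = 3L)
}

# Levenberg-Marquardt NLS with tight convergence control; non-convergence is
# an error carrying the optimiser trace, never a silent result.
.nls_lm <- function(formula, data, start) {
  run <- function(st, ...) {
    minpack.lm::nlsLM(
      formula, data = data, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 200, ...)
    )
  }
  fit <- tryCatch(run(start, ftol = 1e-12, ptol = 1e-12), error = function(e) {
    # exactly interpolating (zero-residual) fits can land so close to a
    # degenerate optimum that the finished model's gradient fails the rank
    # check; refitting at the optimiser's default stopping tolerance keeps
    # the same optimum at a numerically regular point
    if (grepl("singular gradient", conditionMessage(e))) {
      run(lapply(start, function(b) b * (1 + 1e-4) + 1e-6))
    } else {
      abort(conditionMessage(e))
    }
  })
  conv <- fit$convInfo
  # stopCode 1..4 signal gradient/parameter convergence; 5+ mean the
  # iteration budget or a tolerance floor was hit without converging
  if (!is.null(conv) && !isTRUE(conv$isConv)) {
    abort(sprintf("nonlinear fit did not converge after %d iterations (code %s: %s)",
                  conv$finIter, conv$stopCode, conv$stopMessage))
  }
  fit
}

#' Goodness-of-fit statistics
#'
#' `R^2 = 1 - SSE/SST` (reported as computed, which can be negative for fits
#' worse than the mean) and `MSE = SSE / (n - n_params)` on residual degrees
#' of freedom.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param n_params Number of fitted parameters (must be < n).
#' @return A one-row tibble with `r.squared`, `mse`, `sse`, `n`,
#'   `df.residual`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4), n_params = 1)
#' @export
goodness_of_fit <- function(observed, predicted, n_params) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  n <- length(observed)
  if (n <= n_params) abort("need more observations than parameters")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) abort("observed values have zero total variance: R^2 undefined")
  sse <- sum((observed - predicted)^2)
  tibble::tibble(
    r.squared = 1 - sse / sst,
    mse = sse / (n - n_params),
    sse = sse,
    n = n,
    df.residual = n - n_params
  )
}

#' @export
print.allo_fit <- function(x, ...) {
  cat(sprintf("<allo_fit: %s on %s, n = %d>\n", x$model_form, x$response_kind, x$stats$n))
  print(x$coefficients)
  cat(sprintf("R^2 = %.4f, MSE = %.5g (df = %d)\n",
              x$stats$r_squared, x$stats$mse, x$stats$df_residual))
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x An `"allo_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy allo_fit
#' @export
tidy.allo_fit <- function(x, ...) x$coefficients

#' One-row summary of an allometric fit
#'
#' @inheritParams tidy.allo_fit
#' @return A one-row tibble: `r.squared`, `mse`, `n`, `df.residual`,
#'   `converged`, `iterations`.
#' @method glance allo_fit
#' @export
glance.allo_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$stats$r_squared,
    mse = x$stats$mse,
    n = x$stats$n,
    df.residual = x$stats$df_residual,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations
  )
}

#' @method augment allo_fit
#' @export
augment.allo_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  d$.fitted <- as.numeric(fitted(x$fit))
  d$.resid <- as.numeric(residuals(x$fit))
  d
}

#' @export
predict.allo_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(as.numeric(fitted(object$fit)))
  as.numeric(predict(object$fit, newdata = newdata))
}

#' Convert an allometric fit to a loadable bark model
#'
#' Packages the point estimates of an [fit_dbh_linear()],
#' [fit_height_rational()] or [fit_power_model()] result as a `bark_model`
#' so it can be used by the prediction and pipeline functions in place of a
#' packaged model.
#'
#' @param x An `"allo_fit"` object.
#' @return A `bark_model` object.
#' @export
as_bark_model <- function(x) {
  stopifnot(inherits(x, "allo_fit"))
  response <- c(dbh_mm = "dbh", height_m = "height",
                thickness_mm = "thickness", radius_cm = "radius")[[x$response_kind]]
  unit <- c(dbh_mm = "mm", height_m = "m", thickness_mm = "mm", radius_cm = "cm")[[x$response_kind]]
  entry <- list(
    form = x$model_form,
    coefficients = as.list(setNames(x$coefficients$estimate, x$coefficients$term)),
    se = as.list(setNames(x$coefficients$std.error, x$coefficients$term)),
    p = as.list(setNames(format(x$coefficients$p.value, digits = 3), x$coefficients$term)),
    r_squared = x$stats$r_squared,
    mse = x$stats$mse
  )
  .new_bark_model(entry, response, unit)
}
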