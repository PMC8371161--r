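#' Linear storage-decay models and agreement statistics
#'
#' Ordinary least squares fits of normalised weight (or freshness) against
#' storage day or density, and the chemometric agreement statistics used
#' to compare a measurement chain against a reference method.
#'
#' @name storage_model
NULL

#' Fit a straight line by ordinary least squares
#'
#' Thin wrapper around [stats::lm()] returning the three quantities the
#' decay models report: slope, intercept and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`. A response with zero
#' variance yields slope 0 and an `NA` R-squared flagged as degenerate
#' (R-squared is undefined, not 0 or 1, when there is nothing to explain).
#'
#' @param x Predictor (e.g. storage day); must not be constant.
#' @param y Response (e.g. normalised weight), same length, n >= 2.
#' @return A list of class `storage_model`: `slope`, `intercept`,
#'   `r_squared`, `n`, `degenerate`.
#' @examples
#' s <- generate_storage_series(
#'   storage_series_spec(60, -0.0028, 30, intercept = 1.0030))
#' fit_linear(s$day, s$normalized_weight)
#' @export
fit_linear <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("`x` and `y` must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate predictor: `x` has zero variance",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- unname(stats::coef(fit))
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) NA_real_ else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = co[2], intercept = co[1], r_squared = r2,
                 n = length(x), degenerate = degenerate),
            class = "storage_model")
}

#' @export
print.storage_model <- function(x, ...) {
  cat(sprintf("<storage_model> y = %.6g x + %.6g  (R^2 %s, n = %d)\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared),
              x$n))
  invisible(x)
}

#' Predict from a fitted storage model
#'
#' @param object A `storage_model`.
#' @param x Predictor value(s).
#' @param ... Unused.
#' @return `intercept + slope * x`.
#' @examples
#' avg <- fit_linear(0:30, 1.0030 - 0.0028 * (0:30))
#' predict(avg, 30)  # 0.919
#' @export
predict.storage_model <- function(object, x, ...) {
  object$intercept + object$slope * x
}

#' Fit the freshness-versus-density relation
#'
#' Identical contract to [fit_linear()], provided as a named entry point:
#' because freshness is defined as `100 * rho / rho_HE`, freshness values
#' produced from the densities themselves lie exactly on a line through
#' the origin with slope `100 / rho_HE`, so this fit returns `R^2 = 1`
#' whenever the inputs are internally consistent.
#'
#' @param densities Egg densities, g/mm^3.
#' @param freshness Freshness percentages.
#' @return A `storage_model`.
#' @export
fit_freshness_density <- function(densities, freshness) {
  fit_linear(densities, freshness)
}

#' Fit a storage series
#'
#' Accepts a data.frame (or CSV path) with columns `day` and either
#' `normalized_weight` or raw `weight`; raw weights are normalised by the
#' day-0 weight before fitting.
#'
#' @param series Data.frame or CSV path.
#' @return A `storage_model` of normalised weight on day.
#' @export
fit_storage <- function(series) {
  if (is.character(series)) series <- utils::read.csv(series)
  stopifnot(is.data.frame(series), "day" %in% names(series))
  if (!"normalized_weight" %in% names(series)) {
    if (!"weight" %in% names(series)) {
      stop("series needs a `normalized_weight` or `weight` column",
           call. = FALSE)
    }
    w0 <- series$weight[match(0, series$day)]
    if (is.na(w0)) stop("day-0 weight required to normalise", call. = FALSE)
    series$normalized_weight <- series$weight / w0
  }
  fit_linear(series$day, series$normalized_weight)
}

#' Agreement statistics between a reference and a measured series
#'
#' Per-item relative errors `|measured - reference| / reference * 100`,
#' their average and maximum, the complementary accuracies, the OLS slope
#' and R-squared of measured on reference, the root mean square error of
#' calibration `RMSEC = sqrt(mean((measured - reference)^2))` and the
#' residual prediction deviation `RPD = SD(reference) / RMSEC`. A perfect
#' chain has zero errors and an infinite RPD (flagged, not an error).
#'
#' @param reference Reference-method values, all > 0.
#' @param measured Values from the chain under test, same length, n >= 2.
#' @return A list of class `agreement_report` with fields
#'   `avg_relative_error`, `max_relative_error`, `avg_accuracy`,
#'   `min_accuracy`, `slope`, `r_squared`, `rmsec`, `rpd`, `n`.
#' @examples
#' agreement_metrics(c(100, 200, 300), c(99, 202, 297))
#' @export
agreement_metrics <- function(reference, measured) {
  if (!is.numeric(reference) || !is.numeric(measured) ||
      length(reference) != length(measured)) {
    stop("`reference` and `measured` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(reference) < 2) stop("need at least 2 items", call. = FALSE)
  .check_positive(reference, "reference")
  rel <- abs(measured - reference) / reference * 100
  rmsec <- sqrt(mean((measured - reference)^2))
  ols <- if (stats::var(reference) > 0) fit_linear(reference, measured) else NULL
  structure(list(
    avg_relative_error = mean(rel),
    max_relative_error = max(rel),
    avg_accuracy = 100 - mean(rel),
    min_accuracy = 100 - max(rel),
    slope = if (is.null(ols)) NA_real_ else ols$slope,
    r_squared = if (is.null(ols)) NA_real_ else ols$r_squared,
    rmsec = rmsec,
    rpd = if (rmsec == 0) Inf else stats::sd(reference) / rmsec,
    n = length(reference)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n = %d\n",
                     "  rel. error avg %.2f %% (max %.2f %%), accuracy avg %.2f %%\n",
                     "  slope %.4f, R^2 %.4f, RMSEC %.4g, RPD %s\n"),
              x$n, x$avg_relative_error, x$max_relative_error, x$avg_accuracy,
              x$slope, x$r_squared, x$rmsec,
              if (is.infinite(x$rpd)) "Inf" else sprintf("%.2f", x$rpd)))
  invisible(x)
}
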