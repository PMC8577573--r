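# BP-history features: resample the irregular BP series onto an even grid
# by linear interpolation, select a (seasonal) ARIMA model by exhaustive
# order search under AICc, and attach one-step-ahead forecasts (SBP_arima,
# DBP_arima) aligned to each BP reading using only grid points strictly
# before the reading.

#' Resample an irregular BP series onto an even grid
#'
#' The grid is anchored at the first reading and stepped every `spacing`
#' hours up to the last reading (no extrapolation).  Each grid value is the
#' linear interpolation of the two readings bracketing the grid point; the
#' `interpolated` mask flags grid points with no reading within
#' `spacing / 2` hours.
#'
#' @param readings BP data.frame (`timestamp`, `sbp`, `dbp`).
#' @param target `"sbp"` or `"dbp"`.
#' @param spacing grid spacing in hours (default 12: two points per day,
#'   matching a twice-daily measurement protocol).
#' @return an `even_series` list: `grid_start` (POSIXct), `spacing`,
#'   `times` (numeric seconds), `values`, `interpolated`.
#' @export
resample_bp_series <- function(readings, target = c("sbp", "dbp"),
                               spacing = 12) {
  target <- match.arg(target)
  if (nrow(readings) < 2) stop_rfsv("need >= 2 BP readings to resample")
  tt <- as.numeric(readings$timestamp)
  yy <- as.numeric(readings[[target]])
  ord <- order(tt)
  tt <- tt[ord]; yy <- yy[ord]
  step <- spacing * 3600
  grid <- seq(tt[1], tt[length(tt)], by = step)
  vals <- approx(tt, yy, xout = grid, method = "linear", ties = "ordered")$y
  near <- vapply(grid, function(g) min(abs(tt - g)), numeric(1))
  structure(list(grid_start = readings$timestamp[ord][1], spacing = spacing,
                 times = grid, values = vals,
                 interpolated = near > step / 2, target = target),
            class = "even_series")
}

#' @export
print.even_series <- function(x, ...) {
  cat(sprintf("<even_series %s> %d points every %g h (%d interpolated)\n",
              x$target, length(x$values), x$spacing, sum(x$interpolated)))
  invisible(x)
}

# AICc from a fitted stats::arima object
aicc <- function(fit) {
  k <- length(coef(fit)) + 1  # + innovation variance
  n <- fit$nobs
  if (n - k - 1 <= 0) return(Inf)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best (seasonal) ARIMA model by exhaustive order search
#'
#' Fits every `(p, d, q)` (and, when `seasonal`, every seasonal
#' `(P, D, Q)` with period `24 / spacing` grid steps = one day) within the
#' bounds and returns the candidate minimizing AICc.  Candidates are
#' visited in order of increasing total order, and a candidate replaces
#' the incumbent only when strictly better, so criterion ties resolve
#' toward fewer parameters.  Candidates that fail to converge are skipped
#' and logged.  A constant (zero-variance) series returns a degenerate
#' random-walk spec without fitting.
#'
#' @param series an `even_series`.
#' @param max_p,max_q,max_d search bounds for the non-seasonal orders.
#' @param seasonal include seasonal orders (bounds `max_P`, `max_D`,
#'   `max_Q`).
#' @param max_P,max_D,max_Q seasonal search bounds.
#' @param criterion only `"aicc"` is implemented.
#' @return an `arima_spec`: orders, seasonal orders, period, coefficients,
#'   `sigma2`, `score` (AICc), the underlying fit, and a `degenerate` flag.
#' @export
fit_best_arima <- function(series, max_p = 3, max_q = 3, max_d = 2,
                           seasonal = TRUE, max_P = 1, max_D = 1, max_Q = 1,
                           criterion = "aicc") {
  stopifnot(inherits(series, "even_series"))
  y <- series$values
  if (length(y) < 8) stop_rfsv("series too short to fit (need >= 8 points)")
  period <- as.integer(round(24 / series$spacing))
  if (sd(y) == 0) {
    rfsv_log("info", "constant series: degenerate random-walk spec returned")
    return(structure(list(order = c(0L, 1L, 0L), seasonal = c(0L, 0L, 0L),
                          period = period, coef = numeric(0), delta = 0,
                          sigma2 = 0, score = -Inf, fit = NULL,
                          degenerate = TRUE, series = series),
                     class = "arima_spec"))
  }
  if (!seasonal) max_P <- max_D <- max_Q <- 0
  grid <- expand.grid(p = 0:max_p, d = 0:max_d, q = 0:max_q,
                      P = 0:max_P, D = 0:max_D, Q = 0:max_Q)
  grid <- grid[grid$d + grid$D <= 3, , drop = FALSE]
  grid <- grid[order(rowSums(grid), grid$p + grid$q + grid$P + grid$Q), ,
               drop = FALSE]
  best <- NULL; best_score <- Inf; n_fail <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- tryCatch(
      suppressWarnings(arima(y, order = c(g$p, g$d, g$q),
                             seasonal = list(order = c(g$P, g$D, g$Q),
                                             period = period))),
      error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1; next }
    score <- aicc(fit)
    if (is.finite(score) && score < best_score - 1e-10) {
      best_score <- score
      best <- list(g = g, fit = fit)
    }
  }
  if (n_fail > 0) rfsv_log("debug", n_fail, " ARIMA candidate(s) failed and were skipped")
  if (is.null(best)) stop_rfsv("all ", nrow(grid), " ARIMA candidates failed to fit")
  g <- best$g; fit <- best$fit
  cf <- coef(fit)
  structure(list(order = c(g$p, g$d, g$q), seasonal = c(g$P, g$D, g$Q),
                 period = period, coef = cf,
                 delta = if ("intercept" %in% names(cf)) unname(cf["intercept"]) else 0,
                 sigma2 = fit$sigma2, score = best_score, fit = fit,
                 degenerate = FALSE, series = series),
            class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("<arima_spec> (%d,%d,%d)(%d,%d,%d)[%d]%s AICc %.2f sigma2 %.3f\n",
              x$order[1], x$order[2], x$order[3],
              x$seasonal[1], x$seasonal[2], x$seasonal[3], x$period,
              if (x$degenerate) " [degenerate]" else "", x$score, x$sigma2))
  invisible(x)
}

# internal: one-step-ahead predictions for every grid index (prediction
# for index i uses grid history strictly before i, via the Kalman
# innovations of the fit), plus the one-step forecast beyond the series end.
one_step_predictions <- function(spec) {
  y <- spec$series$values
  n <- length(y)
  if (spec$degenerate) {
    return(list(within = c(NA_real_, y[-n]), beyond = y[n]))
  }
  within <- y - as.numeric(residuals(spec$fit))
  within[1] <- NA_real_  # no history before the first grid point
  beyond <- as.numeric(predict(spec$fit, n.ahead = 1)$pred)
  list(within = within, beyond = beyond)
}

#' One-step ARIMA forecasts aligned to BP readings
#'
#' For each reading time, emits the fitted model's one-step-ahead
#' prediction from the resampled grid history strictly before that time.
#' Readings before the second grid point get `NA` (insufficient history).
#' For a `(0,1,0)` zero-drift model the forecast equals the last grid
#' value before the reading.
#'
#' @param spec an `arima_spec` from [fit_best_arima()].
#' @param series the `even_series` the spec was fitted on.
#' @param readings BP data.frame with a `timestamp` column.
#' @return numeric vector of forecasts (mmHg), one per reading.
#' @export
arima_one_step_forecasts <- function(spec, series, readings) {
  stopifnot(inherits(spec, "arima_spec"), inherits(series, "even_series"))
  preds <- one_step_predictions(spec)
  gt <- series$times
  n <- length(gt)
  u <- as.numeric(readings$timestamp)
  out <- rep(NA_real_, length(u))
  for (i in seq_along(u)) {
    last <- findInterval(u[i] - 1e-6, gt)  # last grid index strictly before u
    if (last < 1) next                      # before the second grid point
    out[i] <- if (last < n) preds$within[last + 1] else preds$beyond
  }
  out
}

#' Attach SBP_arima / DBP_arima columns to a feature table
#'
#' Resamples the BP series (of `fit_readings`, typically the training
#' rows of a cross-validation fold, to avoid fitting on held-out data),
#' selects the best model per target, and writes one-step forecasts for
#' every row of `table`.
#'
#' @param table a `feature_table`.
#' @param fit_readings BP data.frame used to build and fit the series;
#'   defaults to the table's own `timestamp`/`sbp`/`dbp` columns.
#' @param spacing grid spacing in hours.
#' @param ... search bounds passed to [fit_best_arima()].
#' @return the table with `SBP_arima` and `DBP_arima` feature columns and
#'   an `"arima_specs"` attribute holding the two fitted specs.
#' @export
add_arima_features <- function(table, fit_readings = NULL, spacing = 12, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(fit_readings)) {
    fit_readings <- data.frame(timestamp = table$timestamp,
                               sbp = table$sbp, dbp = table$dbp)
  }
  specs <- list()
  df <- as.data.frame(table)
  for (target in c("sbp", "dbp")) {
    series <- resample_bp_series(fit_readings, target, spacing)
    spec <- fit_best_arima(series, ...)
    col <- paste0(toupper(target), "_arima")
    df[[col]] <- arima_one_step_forecasts(spec, series, table)
    specs[[target]] <- spec
  }
  fn <- union(attr(table, "feature_names"), c("SBP_arima", "DBP_arima"))
  out <- as_feature_table(df, subject_id = attr(table, "subject_id"),
                          feature_names = fn)
  attr(out, "horizon_shift") <- attr(table, "horizon_shift")
  attr(out, "arima_specs") <- specs
  out
}
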