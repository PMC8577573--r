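mk_readings <- function(hours, values) {
  data.frame(timestamp = as.POSIXct("2024-03-01", tz = "UTC") + hours * 3600,
             sbp = values, dbp = values - 40)
}

# even series built directly from values on a regular grid
mk_series <- function(values, spacing = 12) {
  n <- length(values)
  r <- mk_readings(spacing * (seq_len(n) - 1), values)
  resample_bp_series(r, "sbp", spacing = spacing)
}

test_that("resampling interpolates linearly between bracketing readings", {
  r <- mk_readings(c(0, 10), c(120, 130))
  s <- resample_bp_series(r, "sbp", spacing = 5)
  expect_equal(s$values, c(120, 125, 130))
  # grid point at 5 h is the linear midpoint
  expect_equal(s$values[2], 125)
  # readings exactly on the grid reproduce themselves, nothing flagged
  r2 <- mk_readings(c(0, 12, 24), c(118, 126, 122))
  s2 <- resample_bp_series(r2, "sbp", spacing = 12)
  expect_equal(s2$values, c(118, 126, 122))
  expect_false(any(s2$interpolated))
  expect_error(resample_bp_series(r[1, ], "sbp"), ">= 2")
})

test_that("resampled values match the two-point closed form and never extrapolate", {
  set.seed(5)
  hours <- sort(runif(9, 0, 100))
  vals <- 120 + cumsum(rnorm(9, 0, 3))
  r <- mk_readings(hours, vals)
  s <- resample_bp_series(r, "sbp", spacing = 6)
  tt <- as.numeric(r$timestamp)
  for (i in seq_along(s$times)) {
    g <- s$times[i]
    j <- findInterval(g, tt)
    expected <- if (g == tt[j]) vals[j] else
      vals[j] + (vals[j + 1] - vals[j]) * (g - tt[j]) / (tt[j + 1] - tt[j])
    expect_equal(s$values[i], expected, tolerance = 1e-9)
    # interpolation stays within the bracketing readings
    if (g > tt[j]) {
      expect_gte(s$values[i], min(vals[j], vals[j + 1]) - 1e-12)
      expect_lte(s$values[i], max(vals[j], vals[j + 1]) + 1e-12)
    }
  }
  expect_gte(min(s$times), tt[1])
  expect_lte(max(s$times), tt[length(tt)])
})

test_that("exhaustive search prefers white noise orders and random-walk differencing", {
  set.seed(1)
  s_wn <- mk_series(rnorm(200))
  spec_wn <- fit_best_arima(s_wn, max_p = 2, max_q = 2, max_d = 1,
                            seasonal = FALSE)
  expect_equal(spec_wn$order, c(0, 0, 0))
  set.seed(2)
  s_rw <- mk_series(cumsum(rnorm(200)))
  spec_rw <- fit_best_arima(s_rw, max_p = 2, max_q = 1, max_d = 2,
                            seasonal = FALSE)
  expect_gte(spec_rw$order[2], 1)
})

test_that("constant series yields a degenerate random-walk spec without crashing", {
  s <- mk_series(rep(120, 30))
  spec <- fit_best_arima(s, seasonal = FALSE)
  expect_true(spec$degenerate)
  expect_equal(spec$order, c(0L, 1L, 0L))
  expect_equal(spec$sigma2, 0)
  fc <- arima_one_step_forecasts(spec, s, mk_readings(c(100, 200), c(120, 120)))
  expect_equal(fc, c(120, 120))
})

test_that("a zero-drift (0,1,0) model forecasts the last grid value", {
  set.seed(3)
  vals <- 120 + cumsum(rnorm(40, 0, 2))
  s <- mk_series(vals)
  spec <- fit_best_arima(s, max_p = 0, max_q = 0, max_d = 1, seasonal = FALSE)
  expect_equal(spec$order, c(0, 1, 0))
  # readings just after grid points 5, 17 and past the end
  gt <- s$times
  r <- mk_readings((c(gt[6], gt[18], gt[40] + 3600) -
                      as.numeric(as.POSIXct("2024-03-01", tz = "UTC"))) / 3600,
                   c(120, 120, 120))
  fc <- arima_one_step_forecasts(spec, s, r)
  expect_equal(fc, c(vals[5], vals[17], vals[40]))
})

test_that("AR(1) one-step forecasts follow the closed form", {
  set.seed(4)
  n <- 300
  y <- numeric(n)
  for (i in 2:n) y[i] <- 0.6 * y[i - 1] + rnorm(1)
  y <- y + 120
  s <- mk_series(y)
  spec <- fit_best_arima(s, max_p = 1, max_q = 0, max_d = 0, seasonal = FALSE)
  expect_equal(spec$order, c(1, 0, 0))
  a <- unname(spec$coef["ar1"])
  m <- unname(spec$coef["intercept"])
  preds <- rfsv:::one_step_predictions(spec)
  # prediction for grid i from history: mean + ar * (previous - mean)
  i <- 100:110
  expect_equal(preds$within[i], m + a * (y[i - 1] - m), tolerance = 1e-6)
  expect_equal(preds$beyond, m + a * (y[n] - m), tolerance = 1e-6)
})

test_that("differenced forecasts are shift-equivariant", {
  set.seed(6)
  vals <- 100 + cumsum(rnorm(60, 0, 2))
  r1 <- mk_readings(12 * (0:59), vals)
  r2 <- mk_readings(12 * (0:59), vals + 100)
  s1 <- resample_bp_series(r1, "sbp")
  s2 <- resample_bp_series(r2, "sbp")
  sp1 <- fit_best_arima(s1, max_p = 0, max_q = 0, max_d = 1, seasonal = FALSE)
  sp2 <- fit_best_arima(s2, max_p = 0, max_q = 0, max_d = 1, seasonal = FALSE)
  probe <- mk_readings(12 * (5:20) + 1, rep(120, 16))
  expect_equal(arima_one_step_forecasts(sp2, s2, probe),
               arima_one_step_forecasts(sp1, s1, probe) + 100,
               tolerance = 1e-8)
})

test_that("selected model's one-step error approaches the innovation variance", {
  set.seed(7)
  n <- 300
  sigma <- 3
  y <- numeric(n)
  for (i in 2:n) y[i] <- 0.8 * y[i - 1] + rnorm(1, 0, sigma)
  s <- mk_series(y + 130)
  spec <- fit_best_arima(s, max_p = 2, max_q = 1, max_d = 1, seasonal = FALSE)
  preds <- rfsv:::one_step_predictions(spec)
  mse <- mean((s$values - preds$within)[-(1:10)]^2)
  expect_lt(abs(mse / sigma^2 - 1), 0.1)
  # and it clearly beats the mean-only forecast
  expect_lt(mse, mean((s$values - mean(s$values))^2))
})

test_that("one-step forecasts of a fitted AR(1) beat the training mean across seeds", {
  wins <- vapply(1:5, function(sd0) {
    set.seed(30 + sd0)
    n <- 220
    y <- numeric(n)
    for (i in 2:n) y[i] <- 0.7 * y[i - 1] + rnorm(1)
    s <- mk_series(y + 120)
    spec <- fit_best_arima(s, max_p = 1, max_q = 0, max_d = 1, seasonal = FALSE)
    preds <- rfsv:::one_step_predictions(spec)
    mse <- mean((s$values - preds$within)[-1]^2)
    mse < mean((s$values - mean(s$values))^2)
  }, logical(1))
  expect_true(all(wins))
})

test_that("feature columns align with readings and respect history", {
  sim <- cached_sim("small30", simulate_subject(
    sim_profile(days = 14), seed = 5))
  tab <- build_feature_table(sim$dataset)
  tab2 <- add_arima_features(tab, spacing = 12, max_p = 1, max_q = 1,
                             max_d = 1, seasonal = FALSE)
  expect_true(all(c("SBP_arima", "DBP_arima") %in% attr(tab2, "feature_names")))
  expect_equal(nrow(tab2), nrow(tab))
  # the first reading has no grid history
  expect_true(is.na(tab2$SBP_arima[1]))
  expect_true(all(!is.na(tab2$SBP_arima[-1])))
})
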