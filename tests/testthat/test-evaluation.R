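test_that("error metrics match their printed formulas", {
  m <- compute_metrics(c(121, 119), c(120, 120))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  expect_equal(m$mape, 2 * 1 / 240 * 100)  # aggregate percentage form
  perfect <- compute_metrics(c(5, 6, 7), c(5, 6, 7))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$r2, 1)
  expect_error(compute_metrics(1:3, 1:4), "equal")
})

test_that("metrics agree with an independent formula evaluation to 1e-10", {
  set.seed(12)
  for (rep in 1:3) {
    actual <- rnorm(100, 120, 10)
    predicted <- actual + rnorm(100, 0, 5)
    m <- compute_metrics(predicted, actual)
    n <- 100
    mae <- sum(abs(predicted - actual)) / n
    rmse <- sqrt(sum((predicted - actual)^2) / n)
    mape <- n * mae / sum(abs(actual)) * 100
    r2 <- 1 - sum((predicted - actual)^2) / sum((actual - mean(actual))^2)
    expect_equal(m$mae, mae, tolerance = 1e-10)
    expect_equal(m$rmse, rmse, tolerance = 1e-10)
    expect_equal(m$mape, mape, tolerance = 1e-10)
    expect_equal(m$r2, r2, tolerance = 1e-10)
    expect_lte(m$mae, m$rmse)  # Jensen
  }
})

test_that("paired t-test handles identical, degenerate and random inputs", {
  expect_equal(paired_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)
  deg <- paired_ttest(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_true(deg$degenerate)
  set.seed(13)
  a <- rnorm(50, 0.5, 1)
  b <- rnorm(50, 0, 1)
  got <- paired_ttest(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(50))
  pval <- 2 * pt(-abs(tstat), df = 49)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$p_value, pval, tolerance = 1e-10)
  expect_error(paired_ttest(1:2, 1:2), ">= 3")
})

test_that("trend slopes recover linear and constant BP series", {
  o <- as.POSIXct("2024-03-01", tz = "UTC")
  days <- 0:29
  r <- data.frame(timestamp = o + days * 86400, sbp = 120 + 0.5 * days,
                  dbp = 80)
  expect_equal(bp_trend_slope(r, "sbp")$slope, 0.5, tolerance = 1e-12)
  expect_equal(bp_trend_slope(r, "dbp")$slope, 0, tolerance = 1e-12)
  w <- weekly_bp_stats(r)
  expect_equal(w$dbp$first_week$mean, 80)
  expect_equal(w$dbp$last_week$max, 80)
  expect_equal(w$sbp$first_week$mean, mean(120 + 0.5 * 0:6))
  expect_equal(w$sbp$change$mean, 0.5 * 23)
})

test_that("noisy trend slope lies within 3 standard errors of truth", {
  set.seed(14)
  o <- as.POSIXct("2024-03-01", tz = "UTC")
  days <- seq(0, 29.5, by = 0.5)
  r <- data.frame(timestamp = o + days * 86400,
                  sbp = 130 - 0.2 * days + rnorm(60, 0, 4), dbp = 80)
  tr <- bp_trend_slope(r, "sbp")
  fit <- lm(r$sbp ~ days)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(tr$slope - (-0.2)), 3 * se)
})

test_that("cross-validated SimpleMean behaves on degenerate targets", {
  tt <- toy_table(n = 40, k = 3, seed = 15)$table
  tt$sbp <- 120
  cv <- cross_validate(tt, "SimpleMean", "sbp", k = 5, repeats = 1, seed = 1)
  expect_equal(cv$metrics$mae, 0)
  # two-level target: error bounded by the spread
  tt$sbp <- rep(c(100, 140), each = 20)
  cv2 <- cross_validate(tt, "SimpleMean", "sbp", k = 5, repeats = 2, seed = 1)
  expect_gt(cv2$metrics$mae, 0)
  expect_lte(cv2$metrics$mae, 20 * (40 / 32))  # fold means stay within spread
})

test_that("k = n cross-validation reduces to leave-one-out", {
  tt <- toy_table(n = 24, k = 2, n_causal = 2, betas = c(5, -4), seed = 16)$table
  cv <- cross_validate(tt, "SimpleMean", "sbp", k = 24, repeats = 1, seed = 1)
  y <- tt$sbp
  loo <- vapply(seq_along(y), function(i) abs(y[i] - mean(y[-i])), numeric(1))
  expect_equal(cv$metrics$mae, mean(loo), tolerance = 1e-12)
})

test_that("model comparison shares folds across models", {
  sim <- cached_sim("cmp40", simulate_subject(
    sim_profile(days = 30, missing_bp_rate = 0.05), seed = 17))
  cmp <- compare_models(sim$dataset, targets = "sbp",
                        models = c("SimpleMean", "RF"), horizons = 0,
                        k = 5, repeats = 2, seed = 3,
                        params = rf_params(n_trees = 60, seed = 3))
  d <- cmp$detail
  for (r in 1:2) for (f in 1:5) {
    rows_sm <- sort(d$row[d$model == "SimpleMean" & d$repetition == r & d$fold == f])
    rows_rf <- sort(d$row[d$model == "RF" & d$repetition == r & d$fold == f])
    expect_identical(rows_sm, rows_rf)
  }
  expect_equal(sort(unique(cmp$metrics$model)), c("RF", "SimpleMean"))
  # shared folds mean the paired t-test is well-defined
  expect_true(all(cmp$ttests$p_value >= 0 & cmp$ttests$p_value <= 1))
})

test_that("cross-validation is deterministic given the seed", {
  tt <- toy_table(n = 60, k = 4, seed = 18)$table
  a <- cross_validate(tt, "RF", "sbp", k = 5, repeats = 1, seed = 9,
                      params = rf_params(n_trees = 40, seed = 9))
  b <- cross_validate(tt, "RF", "sbp", k = 5, repeats = 1, seed = 9,
                      params = rf_params(n_trees = 40, seed = 9))
  expect_equal(a$metrics, b$metrics)
  expect_equal(a$detail$predicted, b$detail$predicted)
})
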