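# hand-built importance report + table with controlled SHAP/value relations
mk_report <- function(phi, target = "sbp") {
  structure(list(phi = phi, mean_abs = colMeans(abs(phi)), baseline = 120,
                 method = "shap", target = target),
            class = "importance_report")
}

test_that("actionable filter removes clock, heart-rate and BP-history features", {
  expect_equal(actionable_filter(c("heart_rate_1", "speed_24", "steps_72")),
               c("speed_24", "steps_72"))
  expect_equal(actionable_filter(c("SBP_arima", "measure_time")), character(0))
  expect_equal(actionable_filter("sleep_24"), "sleep_24")
  expect_equal(actionable_filter(c("maxHR_48", "slpHR_24", "DBP_arima",
                                   "bed_time_72")), "bed_time_72")
})

test_that("window suffixes collapse to base factors idempotently", {
  expect_equal(collapse_time_windows("steps_24"), "steps")
  expect_equal(collapse_time_windows("steps_48"), "steps")
  expect_equal(collapse_time_windows("deep_sleep_72"), "deep_sleep")
  expect_equal(collapse_time_windows("steps"), "steps")  # idempotent
  expect_equal(collapse_time_windows("mystery_feature"), "mystery_feature")
})

test_that("effect direction follows the SHAP-value association sign", {
  set.seed(30)
  n <- 100
  speed <- rnorm(n, 5, 1)
  bed <- rnorm(n, 23.5, 0.7)
  phi <- cbind(speed_24 = -2 * (speed - mean(speed)),
               bed_time_24 = 1.5 * (bed - mean(bed)))
  df <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                     3600 * seq_len(n),
                   speed_24 = speed, bed_time_24 = bed, sbp = 120, dbp = 80)
  tab <- wrap_table(df)
  rep <- mk_report(phi)
  expect_equal(effect_direction(rep, tab, "speed_24")$direction, "increase")
  expect_equal(effect_direction(rep, tab, "bed_time_24")$direction, "decrease")
})

test_that("unassociated SHAP values yield 'regularize'", {
  n <- 100
  hits <- vapply(1:10, function(s) {
    set.seed(40 + s)
    v <- rnorm(n)
    phi <- cbind(speed_24 = rnorm(n))  # independent of the value
    df <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                       3600 * seq_len(n), speed_24 = v, sbp = 120, dbp = 80)
    effect_direction(mk_report(phi), wrap_table(df), "speed_24")$direction ==
      "regularize"
  }, logical(1))
  # |r| < 0.2 holds for ~95% of null samples at n = 100
  expect_gte(sum(hits), 8)
})

test_that("recommendations skip non-actionable top features and rank families", {
  set.seed(31)
  n <- 80
  feats <- c("heart_rate_1", "speed_24", "steps_72", "steps_24", "SBP_arima")
  vals <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, feats))
  # importance order: heart_rate_1 > speed_24 > steps_72 > steps_24 > SBP_arima
  phi <- cbind(heart_rate_1 = 3 * vals[, 1], speed_24 = -2 * vals[, 2],
               steps_72 = -1.5 * vals[, 3], steps_24 = -1 * vals[, 4],
               SBP_arima = 0.5 * vals[, 5])
  df <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                     43200 * seq_len(n), vals, sbp = rnorm(n, 125, 5),
                   dbp = rnorm(n, 80, 4))
  tab <- wrap_table(df)
  fake <- structure(list(importance = mk_report(phi), target = "sbp"),
                    class = "rfsv_model")
  rep <- generate_recommendations(fake, tab, top_n = 3)
  recs <- rep$recommendations
  # heart_rate_1 and SBP_arima are excluded; families ranked speed > steps
  expect_equal(recs$base_factor[1], "speed")
  expect_equal(recs$direction[1], "increase")
  expect_equal(recs$base_factor[2], "steps")
  # steps_72 and steps_24 collapse into one family (max importance wins)
  expect_equal(recs$source_feature[2], "steps_72")
  expect_equal(nrow(recs), 2)
  expect_true(any(grepl("fewer actionable", rep$flags)))
  expect_true(any(grepl("not actionable", rep$flags)))
  # never recommend an excluded family
  expect_false(any(recs$base_factor %in% c("heart_rate", "SBP_arima")))
  # BP summary comes from the table's readings
  expect_equal(rep$bp_summary$sbp$mean, mean(df$sbp))
  expect_equal(rep$bp_summary$dbp$max, max(df$dbp))
})

test_that("all-excluded feature sets give an empty, flagged report", {
  set.seed(32)
  n <- 40
  phi <- cbind(measure_time = rnorm(n), SBP_arima = rnorm(n))
  df <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                     43200 * seq_len(n), measure_time = rnorm(n),
                   SBP_arima = rnorm(n), sbp = rnorm(n, 125, 5),
                   dbp = rnorm(n, 80, 4))
  fake <- structure(list(importance = mk_report(phi), target = "sbp"),
                    class = "rfsv_model")
  rep <- generate_recommendations(fake, wrap_table(df))
  expect_null(rep$recommendations)
  expect_true(any(grepl("no actionable", rep$flags)))
})

test_that("recommendation output is deterministic", {
  tt <- toy_table(n = 60, k = 4, seed = 33)$table
  # rename features into the wearable naming scheme so collapsing applies
  names(tt)[2:5] <- attr(tt, "feature_names") <-
    c("steps_24", "steps_48", "sleep_24", "bed_time_24")
  fit <- train_rfsv(tt, "sbp", rf_params(n_trees = 40, seed = 2),
                    background_size = 30)
  r1 <- generate_recommendations(fit, tt)
  r2 <- generate_recommendations(fit, tt)
  expect_equal(r1$recommendations, r2$recommendations)
  expect_equal(r1$trend$sbp$slope, r2$trend$sbp$slope)
})
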