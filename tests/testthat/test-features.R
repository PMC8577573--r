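test_that("age-predicted maximum heart rate and zone boundaries", {
  expect_equal(compute_hr_max(40), 180)
  expect_equal(compute_hr_max(20), 200)
  expect_error(compute_hr_max(220), "age")
  expect_error(compute_hr_max(15), "age")
  z <- hr_zones(20)
  expect_equal(z$boundaries, c(100, 140, 200))
  expect_equal(assign_hr_zone(c(90, 120, 150), z), c(1L, 2L, 3L))
  # boundary inclusivity: zone upper bounds belong to the lower zone
  expect_equal(assign_hr_zone(c(100, 140), z), c(1L, 2L))
  expect_true(is.na(assign_hr_zone(NA, z)))
})

test_that("activity levels follow the steps/zone rule", {
  z <- hr_zones(20)  # hr_max 200
  expect_equal(classify_active_level(5, 150, z), "sedentary")   # few steps
  expect_equal(classify_active_level(60, 90, z), "sedentary")   # zone 1
  expect_equal(classify_active_level(60, 120, z), "lightly_active")
  expect_equal(classify_active_level(60, 150, z), "very_active")
  expect_equal(classify_active_level(60, NA, z), "sedentary")   # missing HR
})

test_that("constant-stream window aggregates match closed forms", {
  # 100 steps/min, HR 60, speed 5; age 40 so HR 60 is zone 1 -> sedentary
  ds <- constant_dataset(hours = 96, steps = 100, hr = 60, speed = 5,
                         bp_times = as.POSIXct("2024-03-01", tz = "UTC") + 87 * 3600)
  row <- extract_window_features(ds, ds$bp$timestamp[1])
  expect_equal(row$steps_24, 144000)
  expect_equal(row$steps_48, 144000)  # average of two identical daily totals
  expect_equal(row$steps_72, 144000)
  expect_equal(row$heart_rate_24, 60)
  expect_equal(row$maxHR_24, 60)
  expect_equal(row$heart_rate_1, 60)
  expect_equal(row$speed_24, 5)
  expect_equal(row$sedentary_24, 1440)  # zone 1 overrides the step count
  expect_equal(row$lightly_active_24, 0)
  expect_equal(row$very_active_24, 0)
  # single 23:00-07:00 all-light session in the 24 h window
  expect_equal(row$sleep_24, 8)
  expect_equal(row$light_sleep_24, 8)
  expect_equal(row$rem_sleep_24, 0)
  expect_equal(row$bed_time_24, 23)
  expect_equal(row$up_time_24, 7)
  expect_equal(row$slpHR_24, 60)
  expect_equal(row$measure_time, 15)
})

test_that("activity minutes plus unrecorded minutes conserve the window", {
  sim <- cached_sim("drop30", simulate_subject(
    sim_profile(days = 10, wearable_dropout_rate = 0.1, missing_bp_rate = 0),
    seed = 8))
  tab <- build_feature_table(sim$dataset, impute = FALSE)
  ctx <- rfsv:::feature_context(sim$dataset)
  for (i in c(1, 5, nrow(tab))) {
    e <- as.numeric(tab$timestamp[i])
    recorded <- length(rfsv:::idx_in(ctx, e - 86400, e))
    expect_equal(tab$sedentary_24[i] + tab$lightly_active_24[i] +
                   tab$very_active_24[i] + (1440 - recorded), 1440)
  }
})

test_that("whole-day time shifts leave features unchanged", {
  t1 <- as.POSIXct("2024-03-01", tz = "UTC") + 87 * 3600
  ds1 <- constant_dataset(bp_times = t1, origin = "2024-03-01")
  ds2 <- constant_dataset(bp_times = t1 + 4 * 86400, origin = "2024-03-05")
  r1 <- extract_window_features(ds1, ds1$bp$timestamp[1])
  r2 <- extract_window_features(ds2, ds2$bp$timestamp[1])
  expect_equal(r1, r2)
})

test_that("window aggregates are invariant to minute-record insertion order", {
  sim <- cached_sim("small30", simulate_subject(
    sim_profile(days = 14), seed = 5))
  ds <- sim$dataset
  set.seed(2)
  shuffled <- subject_dataset(ds$subject_id, ds$age,
                              ds$minutes[sample(nrow(ds$minutes)), ],
                              ds$sleep, ds$bp)
  expect_equal(build_feature_table(shuffled, impute = FALSE),
               build_feature_table(ds, impute = FALSE))
})

test_that("horizon shifts drop readings without look-back coverage", {
  o <- as.POSIXct("2024-03-01", tz = "UTC")
  ds <- constant_dataset(hours = 96, bp_times = o + c(30, 78) * 3600)
  t0 <- build_feature_table(ds, horizon_shift = 0, impute = FALSE)
  t24 <- build_feature_table(ds, horizon_shift = 24, impute = FALSE)
  expect_equal(nrow(t0), 2)
  expect_equal(nrow(t24), 1)  # first reading's shifted window precedes data
  expect_equal(attr(t24, "n_dropped"), 1)
  ds1 <- constant_dataset(hours = 96, bp_times = o + 30 * 3600)
  expect_error(build_feature_table(ds1, horizon_shift = 48, impute = FALSE),
               "dropped")
  expect_error(build_feature_table(ds, horizon_shift = 13), "horizon")
})

test_that("simulated 90-day protocol yields one row per reading at horizon 0", {
  sim <- cached_sim("full90", simulate_subject(
    sim_profile(days = 90, missing_bp_rate = 0), seed = 11))
  tab <- build_feature_table(sim$dataset)
  expect_equal(nrow(tab), 180)
})

test_that("same-session readings collapse under the mean dedup policy", {
  o <- as.POSIXct("2024-03-01", tz = "UTC")
  ds <- constant_dataset(hours = 96, bp_times = o + c(80, 80.5) * 3600,
                         sbp = 120, dbp = 80)
  ds$bp$sbp <- c(118, 124)
  ds$bp$dbp <- c(78, 84)
  tm <- build_feature_table(ds, dedup_policy = "mean", impute = FALSE)
  expect_equal(nrow(tm), 1)
  expect_equal(tm$sbp, 121)
  expect_equal(tm$dbp, 81)
  tn <- build_feature_table(ds, dedup_policy = "none", impute = FALSE)
  expect_equal(nrow(tn), 2)
})

test_that("imputation fills missing cells with training medians and flags them", {
  tt <- toy_table(n = 30, k = 3, seed = 4)$table
  tt$f01[c(2, 9)] <- NA
  raw <- tt
  imp <- impute_features(raw)
  expect_false(anyNA(imp$f01))
  expect_equal(imp$f01[2], median(raw$f01, na.rm = TRUE))
  expect_true(all(attr(imp, "imputed")[c(2, 9), "f01"]))
  # fold-honest path: external medians are applied verbatim
  med <- c(f01 = 0.5, f02 = 0, f03 = 0)
  imp2 <- impute_features(raw, medians = med)
  expect_equal(imp2$f01[2], 0.5)
})
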