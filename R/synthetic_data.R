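# Synthetic wearable-data simulator.  Emits cohorts of subject_datasets
# with circadian heart rate, Poisson-seeded walking bouts, nightly sleep
# architecture, twice-daily jittered BP readings, and a configurable
# generative BP model: base level + planted linear lifestyle effects on
# standardized features + AR(1) residual noise.  Because the planted
# effects are computed through the same window-extraction code the
# features module uses, downstream recovery of the effects is exact in the
# zero-noise limit.

#' Specify a planted lifestyle effect
#'
#' @param feature_name engineered feature name (e.g. `"steps_24"`).
#' @param coefficient effect size in mmHg per standardized feature unit.
#' @param applies_to `"sbp"`, `"dbp"` or `"both"`.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(feature_name, coefficient,
                        applies_to = c("both", "sbp", "dbp")) {
  applies_to <- match.arg(applies_to)
  if (!feature_name %in% canonical_feature_names()) {
    stop_rfsv("unknown feature name in effect_spec: ", feature_name)
  }
  if (!is.finite(coefficient)) stop_rfsv("effect coefficient must be finite")
  structure(list(feature_name = feature_name, coefficient = coefficient,
                 applies_to = applies_to), class = "effect_spec")
}

#' Analytic standardization constants for the generative BP model
#'
#' Fixed per-feature location/scale constants used to standardize features
#' inside the generator.  Using fixed constants (rather than sample
#' statistics) keeps the planted ground truth independent of the realized
#' sample.
#'
#' @return data.frame with columns `feature`, `mu`, `sd`.
#' @export
feature_scale_constants <- function() {
  fam <- list(
    steps = c(9000, 4500), sedentary = c(1340, 50),
    lightly_active = c(40, 30), very_active = c(33, 30),
    floors = c(20, 4.5), speed = c(5.25, 0.9),
    heart_rate = c(63, 2), maxHR = c(130, 15),
    sleep = c(7.4, 0.75), light_sleep = c(4.0, 1.5),
    rem_sleep = c(1.9, 1.3), deep_sleep = c(1.5, 1.2),
    bed_time = c(23.5, 0.72), up_time = c(6.85, 1.0), slpHR = c(51.5, 0.6))
  rows <- list(data.frame(feature = "measure_time", mu = 14, sd = 5.5),
               data.frame(feature = "heart_rate_1", mu = 66, sd = 11))
  for (w in c(24, 48, 72)) {
    for (f in names(fam)) {
      rows[[length(rows) + 1]] <-
        data.frame(feature = paste0(f, "_", w),
                   mu = fam[[f]][1],
                   # daily averages fluctuate less over longer windows
                   sd = fam[[f]][2] / sqrt(w / 24))
    }
  }
  do.call(rbind, rows)
}

#' Simulation profile for one subject
#'
#' Defaults describe the emulated home-monitoring protocol: 90 days of
#' minute-level wearable data with twice-daily BP measurements (morning
#' ~08:30, evening ~19:30) and realistic imperfections — measurement-time
#' jitter, skipped measurements and per-minute wearable dropout.  The
#' default planted effects make more daily steps and a lower resting heart
#' rate lower BP and a later bedtime raise it.
#'
#' @param age subject age in years.
#' @param days number of study days with BP measurements (>= 7).
#' @param bp_base_sbp,bp_base_dbp baseline BP levels (mmHg).
#' @param ar_coefficient AR(1) coefficient of the residual process, |.| < 1.
#' @param noise_sd innovation SD of the residual process (mmHg).
#' @param effects list of [effect_spec()] planted lifestyle effects.
#' @param missing_bp_rate probability a scheduled BP reading is skipped.
#' @param bp_time_jitter_sd SD of measurement-time jitter (minutes).
#' @param wearable_dropout_rate probability a minute record is lost.
#' @param bedtime_mean,bedtime_sd bedtime clock-hour distribution.
#' @param sleep_hours_mean,sleep_hours_sd nightly sleep duration (hours).
#' @param bouts_per_day Poisson mean of daily walking bouts.
#' @return a `sim_profile` list.
#' @export
sim_profile <- function(age = 50, days = 90,
                        bp_base_sbp = 130, bp_base_dbp = 82,
                        ar_coefficient = 0.3, noise_sd = 4,
                        effects = list(
                          effect_spec("steps_24", -5, "both"),
                          effect_spec("bed_time_24", 4, "both"),
                          effect_spec("heart_rate_1", -3, "sbp")),
                        missing_bp_rate = 0.1, bp_time_jitter_sd = 20,
                        wearable_dropout_rate = 0.02,
                        bedtime_mean = 23.5, bedtime_sd = 0.75,
                        sleep_hours_mean = 7.5, sleep_hours_sd = 0.8,
                        bouts_per_day = 3) {
  p <- list(age = age, days = days, bp_base_sbp = bp_base_sbp,
            bp_base_dbp = bp_base_dbp, ar_coefficient = ar_coefficient,
            noise_sd = noise_sd, effects = effects,
            missing_bp_rate = missing_bp_rate,
            bp_time_jitter_sd = bp_time_jitter_sd,
            wearable_dropout_rate = wearable_dropout_rate,
            bedtime_mean = bedtime_mean, bedtime_sd = bedtime_sd,
            sleep_hours_mean = sleep_hours_mean, sleep_hours_sd = sleep_hours_sd,
            bouts_per_day = bouts_per_day)
  validate_profile(p)
  structure(p, class = "sim_profile")
}

validate_profile <- function(p) {
  if (p$days < 7) stop_rfsv("profile: days must be >= 7")
  if (p$noise_sd < 0) stop_rfsv("profile: noise_sd must be >= 0")
  if (abs(p$ar_coefficient) >= 1) stop_rfsv("profile: |ar_coefficient| must be < 1")
  for (pr in c("missing_bp_rate", "wearable_dropout_rate")) {
    if (p[[pr]] < 0 || p[[pr]] > 1) stop_rfsv("profile: ", pr, " must be in [0, 1]")
  }
  compute_hr_max(p$age)  # validates age range
  for (ef in p$effects) {
    if (!inherits(ef, "effect_spec")) stop_rfsv("profile: effects must be effect_spec objects")
  }
  invisible(p)
}

# number of wearable lead-in days before the first BP reading, so every
# reading has a full 72-hour look-back
.sim_lead_days <- 3L

#' Simulate one subject
#'
#' Generates the minute-level wearable stream, sleep sessions and BP
#' readings for one subject.  Per BP reading, the generative mean is
#' `base + sum(coefficient * standardized feature)` with features computed
#' from the emitted (post-dropout) stream by the package's own window
#' extraction and standardized with [feature_scale_constants()]; an AR(1)
#' residual (per-reading, per-target) with innovation SD `noise_sd` is
#' added.  Deterministic given `(profile, seed)`.
#'
#' @param profile a [sim_profile()].
#' @param seed integer seed.
#' @param subject_id identifier for the emitted dataset.
#' @return list with elements `dataset` (a `subject_dataset`) and `truth`
#'   (profile, per-reading generative means, planted feature ranking, and
#'   the standardization constants used).
#' @export
simulate_subject <- function(profile, seed, subject_id = "S1") {
  validate_profile(profile)
  set.seed(as.integer(seed))
  origin <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  o <- as.numeric(origin)
  total_days <- profile$days + .sim_lead_days
  zones <- hr_zones(profile$age)

  ## ---- sleep: one episode per night, partitioned into stage segments ----
  sl_start <- numeric(0); sl_end <- numeric(0); sl_stage <- character(0)
  ep_start <- numeric(total_days); ep_end <- numeric(total_days)
  for (d in seq_len(total_days)) {
    bt <- rnorm(1, profile$bedtime_mean, profile$bedtime_sd)      # clock hour
    dur <- min(max(rnorm(1, profile$sleep_hours_mean, profile$sleep_hours_sd),
                   5.5), 10)
    s0 <- o + (d - 1) * 86400 + bt * 3600
    e0 <- s0 + dur * 3600
    ep_start[d] <- s0; ep_end[d] <- e0
    # sequential stage segments filling the night
    pos <- s0
    while (pos < e0 - 60) {
      seg <- min(runif(1, 40, 100) * 60, e0 - pos)
      stg <- sample(c("light", "rem", "deep"), 1, prob = c(0.55, 0.25, 0.20))
      sl_start <- c(sl_start, pos); sl_end <- c(sl_end, pos + seg)
      sl_stage <- c(sl_stage, stg)
      pos <- pos + seg
    }
  }
  sleep <- data.frame(
    start = as.POSIXct(sl_start, tz = "UTC", origin = "1970-01-01"),
    end = as.POSIXct(sl_end, tz = "UTC", origin = "1970-01-01"),
    stage = sl_stage)

  ## ---- minute grid ----
  mt <- o + seq(0, total_days * 86400 - 60, by = 60)
  n <- length(mt)
  ix_range <- function(a, b) {  # minute indices with a <= mt < b
    lo <- bsearch_le(a - 1e-6, mt) + 1L
    hi <- bsearch_le(b - 1e-6, mt)
    if (hi < lo) integer(0) else lo:hi
  }
  asleep <- rep(FALSE, n)
  for (d in seq_len(total_days)) {
    asleep[ix_range(ep_start[d], ep_end[d])] <- TRUE
  }
  hour <- ((mt - o) / 3600) %% 24

  ## ---- walking bouts (awake only) ----
  steps <- ifelse(asleep, 0, rpois(n, 1.5))  # background fidgeting
  speed <- rep(NA_real_, n)
  bout_hr <- rep(0, n)
  for (d in seq_len(total_days)) {
    nb <- rpois(1, profile$bouts_per_day)
    if (nb == 0) next
    day_lo <- o + (d - 1) * 86400
    for (b in seq_len(nb)) {
      b_start <- day_lo + runif(1, 8, 21) * 3600
      b_len <- round(runif(1, 10, 40))
      b_speed <- runif(1, 3, 7.5)
      ix <- ix_range(b_start, b_start + b_len * 60)
      ix <- ix[!asleep[ix]]
      if (length(ix) == 0) next
      steps[ix] <- pmax(round(b_speed * 20 + rnorm(length(ix), 0, 4)), 10)
      speed[ix] <- round(b_speed + rnorm(length(ix), 0, 0.2), 2)
      # raise HR with speed so zone 2/3 minutes occur
      bout_hr[ix] <- pmax(bout_hr[ix], 30 + 10 * (b_speed - 3))
    }
  }

  ## ---- heart rate: circadian baseline + sleep dip + bout elevation ----
  hr_base <- 64 + 6 * sin(2 * pi * (hour - 15) / 24)
  hr <- ifelse(asleep, 52 + 3 * sin(2 * pi * (hour - 4) / 24), hr_base) +
    bout_hr + rnorm(n, 0, 3)
  hr <- pmin(pmax(round(hr, 1), 35), zones$hr_max + 20)
  floors <- ifelse(asleep, 0L, rpois(n, 0.02))

  ## ---- wearable dropout (whole-minute records lost) ----
  keep <- runif(n) >= profile$wearable_dropout_rate
  minutes <- data.frame(
    timestamp = as.POSIXct(mt[keep], tz = "UTC", origin = "1970-01-01"),
    heart_rate = hr[keep], steps = steps[keep], speed = speed[keep],
    floors = floors[keep])

  ## ---- BP measurement schedule ----
  sched <- c()
  for (d in seq_len(profile$days)) {
    day_lo <- o + (.sim_lead_days + d - 1) * 86400
    for (clock in c(8.5, 19.5)) {
      if (runif(1) < profile$missing_bp_rate) next
      sched <- c(sched, day_lo + clock * 3600 +
                   rnorm(1, 0, profile$bp_time_jitter_sd * 60))
    }
  }
  sched <- sort(sched)
  if (length(sched) < 2) stop_rfsv("simulation produced fewer than 2 BP readings")

  ## ---- generative BP model ----
  tmp_ds <- structure(list(subject_id = subject_id, age = profile$age,
                           minutes = minutes, sleep = sleep,
                           bp = data.frame(timestamp = numeric(0))),
                      class = "subject_dataset")
  ctx <- feature_context(tmp_ds)
  consts <- feature_scale_constants()
  eff_feats <- vapply(profile$effects, `[[`, character(1), "feature_name")
  zmat <- matrix(0, length(sched), length(profile$effects))
  if (length(profile$effects) > 0) {
    for (j in seq_along(sched)) {
      row <- window_features_at(ctx, sched[j], list(hr = 0.5, steps = 0.25))
      row[["measure_time"]] <- clock_hour(
        as.POSIXct(sched[j], tz = "UTC", origin = "1970-01-01"))
      for (k in seq_along(profile$effects)) {
        f <- eff_feats[k]
        v <- row[[f]]
        cc <- consts[consts$feature == f, ]
        zmat[j, k] <- if (is.null(v) || is.na(v)) 0 else (v - cc$mu) / cc$sd
      }
    }
  }
  mean_sbp <- rep(profile$bp_base_sbp, length(sched))
  mean_dbp <- rep(profile$bp_base_dbp, length(sched))
  for (k in seq_along(profile$effects)) {
    ef <- profile$effects[[k]]
    if (ef$applies_to %in% c("sbp", "both")) {
      mean_sbp <- mean_sbp + ef$coefficient * zmat[, k]
    }
    if (ef$applies_to %in% c("dbp", "both")) {
      mean_dbp <- mean_dbp + ef$coefficient * zmat[, k]
    }
  }
  ar1 <- function(m) {
    r <- numeric(m)
    eps <- rnorm(m, 0, profile$noise_sd)
    r[1] <- eps[1]
    if (m > 1) for (j in 2:m) r[j] <- profile$ar_coefficient * r[j - 1] + eps[j]
    r
  }
  sbp <- mean_sbp + ar1(length(sched))
  dbp <- mean_dbp + ar1(length(sched))
  dbp <- pmin(dbp, sbp - 5)  # physiological guard: pulse pressure > 0

  bp <- data.frame(
    timestamp = as.POSIXct(sched, tz = "UTC", origin = "1970-01-01"),
    sbp = sbp, dbp = dbp)
  dataset <- subject_dataset(subject_id, profile$age, minutes, sleep, bp)

  ranked <- character(0)
  if (length(profile$effects) > 0) {
    coefs <- vapply(profile$effects, `[[`, numeric(1), "coefficient")
    ranked <- eff_feats[order(abs(coefs), decreasing = TRUE)]
  }
  truth <- structure(list(
    profile = profile, seed = seed,
    means = data.frame(timestamp = bp$timestamp, sbp_mean = mean_sbp,
                       dbp_mean = mean_dbp),
    standardized = setNames(as.data.frame(zmat),
                            if (length(eff_feats)) eff_feats else character(0)),
    planted = ranked,
    effects = profile$effects,
    scale_constants = consts), class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate a cohort of subjects
#'
#' Subject seeds are derived deterministically from `(seed, index)`.  With
#' `heterogeneity > 0`, each subject's effect coefficients are perturbed
#' multiplicatively (log-normal, SD `heterogeneity` on the log scale) to
#' create inter-individual differences in the top lifestyle factor.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profile_template a [sim_profile()] shared by the cohort.
#' @param seed integer cohort seed.
#' @param heterogeneity log-scale SD of per-subject coefficient
#'   perturbations (0 = identical effects for all subjects).
#' @return list of `list(dataset, truth)`, one per subject.
#' @export
simulate_cohort <- function(n_subjects, profile_template, seed,
                            heterogeneity = 0) {
  stopifnot(n_subjects >= 1)
  validate_profile(profile_template)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- profile_template
    if (heterogeneity > 0 && length(prof$effects) > 0) {
      set.seed(derive_seed(seed, 100000 + i))
      prof$effects <- lapply(prof$effects, function(ef) {
        ef$coefficient <- ef$coefficient * exp(rnorm(1, 0, heterogeneity))
        ef
      })
    }
    out[[i]] <- simulate_subject(prof, derive_seed(seed, i),
                                 subject_id = sprintf("SIM%02d", i))
  }
  out
}
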