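# Lifestyle feature engineering: per-minute activity-level discretization
# from heart-rate zones and steps, window aggregates over the 1/24/48/72
# hours preceding each BP reading, sleep-architecture features, and the
# measurement clock time.  One output row per retained BP reading.

#' Age-predicted maximum heart rate
#'
#' `hr_max = 220 - age` (beats/min).
#'
#' @param age age in years, in `[18, 120]`.
#' @return maximum heart rate in beats/min.
#' @export
compute_hr_max <- function(age) {
  if (!is.numeric(age) || any(is.na(age)) || any(age < 18) || any(age > 120)) {
    stop_rfsv("age must be in [18, 120], got ", paste(age, collapse = ", "))
  }
  220 - age
}

#' Heart-rate zone boundaries
#'
#' Three zones with upper bounds at 0.5, 0.7 and 1.0 times the
#' age-predicted maximum heart rate.
#'
#' @param age age in years.
#' @return a list with `hr_max` and the three `boundaries`.
#' @export
hr_zones <- function(age) {
  hm <- compute_hr_max(age)
  list(hr_max = hm, boundaries = c(0.5, 0.7, 1) * hm)
}

#' Assign a heart rate to a zone
#'
#' Zone 1: `hr <= 0.5 hr_max`; zone 2: `0.5 hr_max < hr <= 0.7 hr_max`;
#' zone 3: above.  Vectorized over `hr`; `NA` heart rates give `NA`.
#'
#' @param hr heart rate(s) in beats/min.
#' @param zones result of [hr_zones()].
#' @return integer zone index in `{1, 2, 3}`.
#' @export
assign_hr_zone <- function(hr, zones) {
  b <- zones$boundaries
  ifelse(is.na(hr), NA_integer_,
         ifelse(hr <= b[1], 1L, ifelse(hr <= b[2], 2L, 3L)))
}

#' Classify per-minute activity level
#'
#' Sedentary: fewer than 10 steps in the minute or heart rate in zone 1;
#' lightly active: at least 10 steps and zone 2; very active: at least 10
#' steps and zone 3.  A missing heart rate cannot place the minute in zone 2
#' or 3, so such minutes are classed sedentary; missing steps count as 0.
#'
#' @param steps steps in the minute.
#' @param hr heart rate in beats/min (NA allowed).
#' @param zones result of [hr_zones()].
#' @return character vector in `{"sedentary", "lightly_active", "very_active"}`.
#' @export
classify_active_level <- function(steps, hr, zones) {
  steps <- ifelse(is.na(steps), 0, steps)
  zone <- assign_hr_zone(hr, zones)
  out <- rep("sedentary", length(steps))
  active <- steps >= 10 & !is.na(zone) & zone >= 2
  out[active & zone == 2] <- "lightly_active"
  out[active & zone == 3] <- "very_active"
  out
}

.window_families <- c("steps", "sedentary", "lightly_active", "very_active",
                      "floors", "speed", "heart_rate", "maxHR",
                      "sleep", "light_sleep", "rem_sleep", "deep_sleep",
                      "bed_time", "up_time", "slpHR")

#' Canonical feature-name order
#'
#' The fixed ordering used for tie-breaking in feature selection:
#' `measure_time`, `heart_rate_1`, then each window family at 24, 48 and 72
#' hours, then (optionally) the BP-history forecast columns.
#'
#' @param include_arima append `SBP_arima` and `DBP_arima`.
#' @return character vector of feature names.
#' @export
canonical_feature_names <- function(include_arima = FALSE) {
  nm <- c("measure_time", "heart_rate_1",
          unlist(lapply(c(24, 48, 72), function(w) paste0(.window_families, "_", w))))
  if (include_arima) nm <- c(nm, "SBP_arima", "DBP_arima")
  nm
}

# internal: merge sleep-stage sessions into whole-night episodes.
# Sessions separated by at most `gap` seconds belong to one episode.
sleep_episodes <- function(sleep, gap = 3600) {
  if (nrow(sleep) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  s <- as.numeric(sleep$start)
  e <- as.numeric(sleep$end)
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  ep_start <- s[1]; ep_end <- e[1]
  starts <- c(); ends <- c()
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] - ep_end <= gap) {
        ep_end <- max(ep_end, e[i])
      } else {
        starts <- c(starts, ep_start); ends <- c(ends, ep_end)
        ep_start <- s[i]; ep_end <- e[i]
      }
    }
  }
  starts <- c(starts, ep_start); ends <- c(ends, ep_end)
  data.frame(start = starts, end = ends)
}

# internal: one-time preprocessing of a subject_dataset for fast repeated
# window extraction.
feature_context <- function(dataset) {
  zones <- hr_zones(dataset$age)
  m <- dataset$minutes
  mt <- as.numeric(m$timestamp)
  level <- classify_active_level(m$steps, m$heart_rate, zones)
  eps <- sleep_episodes(dataset$sleep)
  in_sleep <- rep(FALSE, length(mt))
  if (nrow(eps) > 0 && length(mt) > 0) {
    for (i in seq_len(nrow(eps))) {
      lo <- bsearch_le(eps$start[i], mt) + 1L
      hi <- bsearch_le(eps$end[i], mt)
      if (hi >= lo) in_sleep[lo:hi] <- TRUE
    }
  }
  hr <- m$heart_rate
  steps <- ifelse(is.na(m$steps), 0, m$steps)
  floors <- ifelse(is.na(m$floors), 0, m$floors)
  speed <- m$speed
  cs <- function(v) c(0, cumsum(v))
  list(zones = zones, mt = mt,
       hr = hr, steps = steps, speed = speed, floors = floors,
       level = level, in_sleep = in_sleep,
       # prefix sums for O(log n) window aggregates
       c_steps = cs(steps), c_floors = cs(floors),
       c_sed = cs(level == "sedentary"),
       c_light = cs(level == "lightly_active"),
       c_very = cs(level == "very_active"),
       c_hr = cs(ifelse(is.na(hr), 0, hr)), c_hrn = cs(!is.na(hr)),
       c_spd = cs(ifelse(is.na(speed), 0, speed)), c_spdn = cs(!is.na(speed)),
       c_shr = cs(ifelse(in_sleep & !is.na(hr), hr, 0)),
       c_shrn = cs(in_sleep & !is.na(hr)),
       sleep = dataset$sleep,
       sleep_start = as.numeric(dataset$sleep$start),
       sleep_end = as.numeric(dataset$sleep$end),
       sleep_stage = as.character(dataset$sleep$stage),
       episodes = eps)
}

# prefix-sum total of a channel over minute records in (a, b]
win_sum <- function(ctx, cum, a, b) {
  lo <- bsearch_le(a, ctx$mt)
  hi <- bsearch_le(b, ctx$mt)
  cum[hi + 1] - cum[lo + 1]
}

# internal: indices of minute records in (a, b]
idx_in <- function(ctx, a, b) {
  lo <- bsearch_le(a, ctx$mt) + 1L
  hi <- bsearch_le(b, ctx$mt)
  if (hi < lo) integer(0) else lo:hi
}

# shifted clock for bedtimes: hours in [12, 36) so 23:30 and 00:30 are
# numerically adjacent across midnight
shifted_clock <- function(hour) ifelse(hour < 12, hour + 24, hour)

# internal: window features for one reading. `e` = window end (numeric secs).
window_features_at <- function(ctx, e, min_coverage) {
  out <- list()
  for (w in c(24, 48, 72)) {
    ndays <- w / 24
    wsec <- w * 3600
    lo <- bsearch_le(e - wsec, ctx$mt)
    hi <- bsearch_le(e, ctx$mt)
    n_present <- hi - lo
    n_hr <- win_sum(ctx, ctx$c_hrn, e - wsec, e)
    steps_ok <- n_present / (w * 60) >= min_coverage$steps
    hr_ok <- n_hr / (w * 60) >= min_coverage$hr
    speed_ok <- n_present / (w * 60) >= min_coverage$hr

    # per-24h-block totals, averaged across blocks (raw sum when w = 24)
    blk <- function(cum) {
      tot <- numeric(ndays)
      for (i in seq_len(ndays)) {
        tot[i] <- win_sum(ctx, cum, e - i * 86400, e - (i - 1) * 86400)
      }
      mean(tot)
    }
    out[[paste0("steps_", w)]] <- if (steps_ok) blk(ctx$c_steps) else NA_real_
    out[[paste0("floors_", w)]] <- if (steps_ok) blk(ctx$c_floors) else NA_real_
    out[[paste0("sedentary_", w)]] <- if (steps_ok) blk(ctx$c_sed) else NA_real_
    out[[paste0("lightly_active_", w)]] <- if (steps_ok) blk(ctx$c_light) else NA_real_
    out[[paste0("very_active_", w)]] <- if (steps_ok) blk(ctx$c_very) else NA_real_
    out[[paste0("heart_rate_", w)]] <-
      if (hr_ok && n_hr > 0) win_sum(ctx, ctx$c_hr, e - wsec, e) / n_hr else NA_real_
    out[[paste0("maxHR_", w)]] <- if (hr_ok && n_hr > 0) {
      hrw <- ctx$hr[(lo + 1):hi]
      max(hrw, na.rm = TRUE)
    } else NA_real_
    n_spd <- win_sum(ctx, ctx$c_spdn, e - wsec, e)
    out[[paste0("speed_", w)]] <-
      if (speed_ok && n_spd > 0) win_sum(ctx, ctx$c_spd, e - wsec, e) / n_spd else NA_real_

    # sleep durations: sessions clipped to the window, hours, daily average
    dur <- pmax(pmin(ctx$sleep_end, e) - pmax(ctx$sleep_start, e - wsec), 0) / 3600
    tot_by_stage <- c(light = 0, rem = 0, deep = 0)
    if (length(dur) && any(dur > 0)) {
      for (stg in c("light", "rem", "deep")) {
        tot_by_stage[[stg]] <- sum(dur[ctx$sleep_stage == stg])
      }
    }
    out[[paste0("sleep_", w)]] <- sum(tot_by_stage) / ndays
    out[[paste0("light_sleep_", w)]] <- tot_by_stage[["light"]] / ndays
    out[[paste0("rem_sleep_", w)]] <- tot_by_stage[["rem"]] / ndays
    out[[paste0("deep_sleep_", w)]] <- tot_by_stage[["deep"]] / ndays

    # bed/up time from the main (longest) sleep episode per day, most recent
    # `ndays` days with an episode ending in the window
    eps <- ctx$episodes
    if (nrow(eps) > 0) {
      sel <- eps$end > e - wsec & eps$end <= e
      eps <- eps[sel, , drop = FALSE]
    }
    if (nrow(eps) > 0) {
      day <- floor(eps$end / 86400)
      len <- eps$end - eps$start
      main <- do.call(rbind, lapply(split(seq_len(nrow(eps)), day), function(ii) {
        eps[ii[which.max(len[ii])], , drop = FALSE]
      }))
      main <- main[order(main$end, decreasing = TRUE), , drop = FALSE]
      main <- head(main, ndays)
      bt <- shifted_clock(clock_hour(as.POSIXct(main$start, tz = "UTC",
                                                origin = "1970-01-01")))
      ut <- clock_hour(as.POSIXct(main$end, tz = "UTC", origin = "1970-01-01"))
      out[[paste0("bed_time_", w)]] <- mean(bt)
      out[[paste0("up_time_", w)]] <- mean(ut)
    } else {
      out[[paste0("bed_time_", w)]] <- NA_real_
      out[[paste0("up_time_", w)]] <- NA_real_
    }

    n_shr <- win_sum(ctx, ctx$c_shrn, e - wsec, e)
    out[[paste0("slpHR_", w)]] <-
      if (n_shr > 0) win_sum(ctx, ctx$c_shr, e - wsec, e) / n_shr else NA_real_
  }
  n_hr1 <- win_sum(ctx, ctx$c_hrn, e - 3600, e)
  out[["heart_rate_1"]] <-
    if (n_hr1 / 60 >= min_coverage$hr) {
      win_sum(ctx, ctx$c_hr, e - 3600, e) / n_hr1
    } else NA_real_
  out
}

#' Extract the feature row for one BP reading time
#'
#' Aggregates the minute stream and sleep sessions over the half-open
#' windows `(e - w, e]`, `w` in 1/24/48/72 hours, where
#' `e = t_end - horizon_shift` — the feature windows end `horizon_shift`
#' hours before the reading so the model predicts that far ahead.  Sums for
#' steps/floors and activity minutes become per-24h daily averages for the
#' 48/72-hour windows; heart rate and speed are means over recorded
#' minutes; `maxHR` is a max; sleep durations are daily-average hours;
#' bed/up times come from the main sleep episode per day.  Features whose
#' window is recorded below the coverage thresholds are `NA`.
#'
#' @param dataset a `subject_dataset`.
#' @param t_end POSIXct time of the BP reading.
#' @param horizon_shift hours between window end and the reading
#'   (0, 12, 24 or 48).
#' @param min_coverage list with elements `hr` (fraction of window minutes
#'   with a heart-rate value needed for HR/speed features, default 0.5) and
#'   `steps` (fraction of window minutes with any record needed for
#'   step/floor/activity sums, default 0.25).
#' @return a one-row data.frame of features (targets unfilled).
#' @export
extract_window_features <- function(dataset, t_end, horizon_shift = 0,
                                    min_coverage = list(hr = 0.5, steps = 0.25)) {
  ctx <- feature_context(dataset)
  e <- as.numeric(t_end) - horizon_shift * 3600
  if (length(ctx$mt) == 0 || e - 86400 < ctx$mt[1] - 60) {
    stop_rfsv("minute stream does not cover the 24-hour window ending at ",
              format_timestamp(as.POSIXct(e, tz = "UTC", origin = "1970-01-01")))
  }
  row <- window_features_at(ctx, e, min_coverage)
  row[["measure_time"]] <- clock_hour(t_end)
  as.data.frame(row)[c("measure_time", "heart_rate_1",
                       setdiff(canonical_feature_names(), c("measure_time", "heart_rate_1")))]
}

# internal: collapse redundant same-session BP readings.  Readings whose
# consecutive gaps are <= session_gap hours form one measurement session.
dedup_readings <- function(bp, policy = c("mean", "first", "none"),
                           session_gap = 2) {
  policy <- match.arg(policy)
  if (policy == "none" || nrow(bp) <= 1) return(bp)
  tt <- as.numeric(bp$timestamp)
  grp <- cumsum(c(1, diff(tt) > session_gap * 3600))
  if (max(grp) == nrow(bp)) return(bp)
  rows <- lapply(split(seq_len(nrow(bp)), grp), function(ii) {
    if (policy == "first" || length(ii) == 1) return(bp[ii[1], , drop = FALSE])
    data.frame(timestamp = as.POSIXct(mean(tt[ii]), tz = "UTC",
                                      origin = "1970-01-01"),
               sbp = mean(bp$sbp[ii]), dbp = mean(bp$dbp[ii]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the feature table for a subject
#'
#' One row per retained BP reading: redundant same-session readings are
#' collapsed per `dedup_policy` (default: mean within a 2-hour session),
#' readings whose shifted 24-hour window precedes the minute stream are
#' dropped (and counted), window features are extracted via
#' [extract_window_features()], and missing feature cells are imputed with
#' the subject-level median (imputation flags retained in the `"imputed"`
#' attribute).  Set `impute = FALSE` to keep the `NA`s, e.g. for
#' fold-honest imputation during cross-validation via [impute_features()].
#'
#' @param dataset a `subject_dataset`.
#' @param horizon_shift prediction horizon in hours (0, 12, 24 or 48).
#' @param dedup_policy `"mean"`, `"first"` or `"none"`.
#' @param min_coverage see [extract_window_features()].
#' @param impute impute missing features with subject medians (default TRUE).
#' @return a `feature_table` with columns `timestamp`, features, `sbp`, `dbp`.
#' @export
build_feature_table <- function(dataset, horizon_shift = 0,
                                dedup_policy = c("mean", "first", "none"),
                                min_coverage = list(hr = 0.5, steps = 0.25),
                                impute = TRUE) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (!horizon_shift %in% c(0, 12, 24, 48)) {
    stop_rfsv("horizon_shift must be one of 0, 12, 24, 48")
  }
  if (nrow(dataset$bp) == 0) stop_rfsv("dataset has no BP readings")
  bp <- dedup_readings(dataset$bp, match.arg(dedup_policy))
  ctx <- feature_context(dataset)
  ee <- as.numeric(bp$timestamp) - horizon_shift * 3600
  feasible <- ee - 86400 >= ctx$mt[1] - 60 &
    vapply(ee, function(e) length(idx_in(ctx, e - 86400, e)) > 0, logical(1))
  n_drop <- sum(!feasible)
  if (n_drop > 0) {
    rfsv_log("info", n_drop, " reading(s) dropped: shifted window lacks look-back data")
  }
  bp <- bp[feasible, , drop = FALSE]
  ee <- ee[feasible]
  if (nrow(bp) == 0) {
    stop_rfsv("all BP readings dropped: no reading has 24 h of wearable ",
              "look-back at horizon ", horizon_shift, " h")
  }
  rows <- lapply(seq_along(ee), function(i) {
    r <- window_features_at(ctx, ee[i], min_coverage)
    r[["measure_time"]] <- clock_hour(bp$timestamp[i])
    as.data.frame(r)
  })
  feats <- do.call(rbind, rows)
  feats <- feats[canonical_feature_names()]
  df <- cbind(data.frame(timestamp = bp$timestamp), feats,
              data.frame(sbp = bp$sbp, dbp = bp$dbp))
  tab <- as_feature_table(df, subject_id = dataset$subject_id,
                          feature_names = canonical_feature_names())
  attr(tab, "horizon_shift") <- horizon_shift
  attr(tab, "n_dropped") <- n_drop
  if (impute) tab <- impute_features(tab) else tab
}

#' Impute missing feature cells with per-feature medians
#'
#' Medians default to the table's own column medians (subject-level); pass
#' `medians` computed on a training fold to impute a held-out fold without
#' leakage.  Features that are entirely missing are imputed with 0 and
#' logged.  The logical imputation mask is stored in the `"imputed"`
#' attribute and the medians used in `"medians"`.
#'
#' @param table a `feature_table`.
#' @param medians optional named numeric vector of imputation values.
#' @return the imputed `feature_table`.
#' @export
impute_features <- function(table, medians = NULL) {
  fn <- attr(table, "feature_names")
  if (is.null(medians)) {
    medians <- vapply(fn, function(f) median(table[[f]], na.rm = TRUE), numeric(1))
  }
  mask <- matrix(FALSE, nrow(table), length(fn), dimnames = list(NULL, fn))
  for (f in fn) {
    miss <- is.na(table[[f]])
    if (!any(miss)) next
    fill <- medians[[f]]
    if (is.na(fill)) {
      rfsv_log("warn", "feature ", f, " entirely missing; imputed with 0")
      fill <- 0
    }
    table[[f]][miss] <- fill
    mask[miss, f] <- TRUE
  }
  attr(table, "imputed") <- mask
  attr(table, "medians") <- medians
  table
}
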