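# Personalized recommendations: rank actionable lifestyle factors by mean
# absolute Shapley importance, collapse time-window variants into one
# factor family, infer the direction of effect from the sign of the
# SHAP-value/feature-value association, and attach supporting BP
# statistics.

# feature families a subject cannot deliberately change: measurement clock
# time, all heart-rate summaries, and the BP-history forecast columns
.non_actionable_patterns <- c("^measure_time$", "^heart_rate_", "^maxHR_",
                              "^slpHR_", "^SBP_arima$", "^DBP_arima$")

#' Filter feature names down to actionable lifestyle factors
#'
#' Removes `measure_time`, every heart-rate feature (`heart_rate_*`,
#' `maxHR_*`, `slpHR_*`) and the BP-history features `SBP_arima` /
#' `DBP_arima`; the remaining names keep their order.
#'
#' @param features character vector of feature names.
#' @return the actionable subset, order preserved.
#' @export
actionable_filter <- function(features) {
  drop <- Reduce(`|`, lapply(.non_actionable_patterns, grepl, x = features))
  features[!drop]
}

#' Collapse a window-suffixed feature name to its base factor
#'
#' Strips the trailing window suffix (`steps_24` -> `steps`,
#' `deep_sleep_72` -> `deep_sleep`); idempotent; unrecognized names are
#' returned unchanged and logged.
#'
#' @param feature_name one or more feature names.
#' @return base factor name(s).
#' @export
collapse_time_windows <- function(feature_name) {
  vapply(feature_name, function(f) {
    base <- sub("_(1|24|48|72)$", "", f)
    if (identical(base, f) &&
        !f %in% c("measure_time", "SBP_arima", "DBP_arima", .window_families)) {
      rfsv_log("debug", "unrecognized feature name left unchanged: ", f)
    }
    base
  }, character(1), USE.NAMES = FALSE)
}

#' Direction of a feature's effect on predicted BP
#'
#' Pearson correlation between the feature's values and its per-sample
#' Shapley values.  Correlation at or below `-threshold`: higher values
#' lower predicted BP, so recommend an increase; at or above `+threshold`:
#' recommend a decrease; otherwise the association is weak or
#' non-monotone and the recommendation is to regularize the factor.
#'
#' @param report an `importance_report` with per-sample SHAP values.
#' @param table the `feature_table` the report was computed on.
#' @param feature feature name.
#' @param threshold correlation threshold (default 0.2).
#' @return list with `direction` (`"increase"`, `"decrease"`,
#'   `"regularize"`) and the `correlation`.
#' @export
effect_direction <- function(report, table, feature, threshold = 0.2) {
  stopifnot(inherits(report, "importance_report"))
  if (is.null(report$phi)) {
    stop_rfsv("effect_direction needs per-sample SHAP values (method='shap')")
  }
  if (!feature %in% colnames(report$phi)) {
    stop_rfsv("no SHAP column for feature ", feature)
  }
  v <- as.numeric(table[[feature]])
  phi <- report$phi[, feature]
  if (sd(v) == 0 || sd(phi) == 0) {
    rfsv_log("debug", "zero variance for ", feature, ": direction regularize")
    return(list(direction = "regularize", correlation = NA_real_))
  }
  r <- cor(v, phi)
  direction <- if (r <= -threshold) "increase"
  else if (r >= threshold) "decrease"
  else "regularize"
  list(direction = direction, correlation = r)
}

#' Generate top-N personalized lifestyle recommendations
#'
#' Ranks the model's features by mean absolute Shapley value, drops
#' non-actionable ones, collapses window variants into base factor
#' families (family importance = max over its window variants), and
#' reports the `top_n` distinct families with their direction of effect
#' and the subject's BP summary and trend slopes.
#'
#' @param rfsv a trained `rfsv_model` (SHAP importance).
#' @param table the `feature_table` used for training.
#' @param top_n number of recommendations (default 3).
#' @param threshold direction threshold, see [effect_direction()].
#' @return a `subject_report`: `recommendations` data.frame (rank,
#'   base_factor, source_feature, direction, mean_abs_shap, correlation),
#'   `bp_summary`, `trend`, `flags`.
#' @export
generate_recommendations <- function(rfsv, table, top_n = 3, threshold = 0.2) {
  stopifnot(inherits(rfsv, "rfsv_model"))
  report <- rfsv$importance
  if (report$method != "shap") {
    stop_rfsv("recommendations require SHAP importance")
  }
  imp <- report$mean_abs
  keep <- actionable_filter(names(imp))
  flags <- character(0)
  skipped <- setdiff(names(sort(imp, decreasing = TRUE)), keep)
  if (length(skipped) && max(imp[skipped]) >= max(c(imp[keep], 0))) {
    flags <- c(flags, "top feature not actionable; next actionable factor promoted")
  }
  recs <- NULL
  if (length(keep) > 0) {
    fam <- collapse_time_windows(keep)
    fam_imp <- tapply(imp[keep], fam, max)
    src <- vapply(names(fam_imp), function(fm) {
      v <- imp[keep][fam == fm]
      names(v)[order(-v)[1]]
    }, character(1))
    ord <- order(-fam_imp, match(src, names(imp)))  # stable canonical ties
    n_take <- min(top_n, length(fam_imp))
    if (n_take < top_n) flags <- c(flags, "fewer actionable factors than requested")
    take <- ord[seq_len(n_take)]
    rows <- lapply(seq_along(take), function(i) {
      fm <- names(fam_imp)[take[i]]
      dir <- effect_direction(report, table, src[[fm]], threshold)
      data.frame(rank = i, base_factor = fm, source_feature = src[[fm]],
                 direction = dir$direction,
                 mean_abs_shap = unname(fam_imp[take[i]]),
                 correlation = dir$correlation)
    })
    recs <- do.call(rbind, rows)
  } else {
    flags <- c(flags, "no actionable features available")
  }
  readings <- data.frame(timestamp = table$timestamp, sbp = table$sbp,
                         dbp = table$dbp)
  bp_summary <- lapply(c(sbp = "sbp", dbp = "dbp"), function(tg) {
    list(mean = mean(readings[[tg]]), min = min(readings[[tg]]),
         max = max(readings[[tg]]))
  })
  trend <- lapply(c(sbp = "sbp", dbp = "dbp"), function(tg) {
    bp_trend_slope(readings, tg)
  })
  structure(list(subject_id = attr(table, "subject_id"),
                 target = rfsv$target, recommendations = recs,
                 bp_summary = bp_summary, trend = trend,
                 weekly = weekly_bp_stats(readings), flags = flags),
            class = "subject_report")
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report '%s' target=%s>\n", x$subject_id, x$target))
  s <- x$bp_summary
  cat(sprintf("  BP summary: SBP %.1f [%.0f-%.0f]  DBP %.1f [%.0f-%.0f] mmHg\n",
              s$sbp$mean, s$sbp$min, s$sbp$max,
              s$dbp$mean, s$dbp$min, s$dbp$max))
  cat(sprintf("  Trend: SBP %+.3f mmHg/day, DBP %+.3f mmHg/day\n",
              x$trend$sbp$slope, x$trend$dbp$slope))
  if (is.null(x$recommendations)) {
    cat("  No actionable recommendations.\n")
  } else {
    for (i in seq_len(nrow(x$recommendations))) {
      r <- x$recommendations[i, ]
      cat(sprintf("  %d. %s: %s (|SHAP| %.3f mmHg, r=%.2f via %s)\n",
                  r$rank, r$base_factor, r$direction, r$mean_abs_shap,
                  r$correlation, r$source_feature))
    }
  }
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}
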