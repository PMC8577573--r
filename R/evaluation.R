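# Evaluation: error metrics, repeated k-fold cross-validation with
# fold-honest imputation and ARIMA refitting, the
# SimpleMean/ARIMA/RF/RF-ARIMA/RFSV comparison across prediction horizons,
# paired t-tests on per-sample errors, and BP trend statistics.

#' Prediction-error metrics
#'
#' MAE, RMSE, MAPE and the coefficient of determination.  MAPE is the
#' aggregate form `n * MAE / sum(|actual|) * 100`; R-squared is
#' `1 - SSE/SST` (defined as 1 when SSE is 0, `NA` when only SST is 0).
#'
#' @param predicted,actual numeric vectors of equal nonzero length (mmHg).
#' @return an `eval_metrics` list: `mae`, `rmse`, `mape`, `r2`, `n`.
#' @export
compute_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) == 0) {
    stop_rfsv("predicted and actual must have equal nonzero length")
  }
  err <- predicted - actual
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  denom <- sum(abs(actual))
  mape <- if (denom == 0) {
    rfsv_log("warn", "MAPE undefined: sum(|actual|) is 0")
    NA_real_
  } else length(actual) * mae / denom * 100
  sse <- sum(err^2)
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sse == 0) 1 else if (sst == 0) NA_real_ else 1 - sse / sst
  structure(list(mae = mae, rmse = rmse, mape = mape, r2 = r2,
                 n = length(actual)), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f  RMSE %.3f  MAPE %.3f%%  R2 %s  (n=%d)\n",
              x$mae, x$rmse, x$mape,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)), x$n))
  invisible(x)
}

#' Paired Student's t-test on per-sample errors
#'
#' Two-sided paired t-test on the differences of two equal-length,
#' sample-aligned error vectors.  All-zero differences give `p = 1`;
#' constant nonzero differences (zero variance) are flagged degenerate.
#'
#' @param errors_a,errors_b per-sample (absolute) errors of two models on
#'   the same samples.
#' @return list with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_ttest <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b) || length(errors_a) < 3) {
    stop_rfsv("need equal-length paired error vectors of length >= 3")
  }
  d <- errors_a - errors_b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(statistic = 0, p_value = 1, df = length(d) - 1,
                  mean_difference = 0, degenerate = FALSE))
    }
    rfsv_log("warn", "paired t-test degenerate: constant nonzero differences")
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                df = length(d) - 1, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Longitudinal BP trend slope
#'
#' Ordinary least-squares slope of BP against time in days.
#'
#' @param readings BP data.frame (`timestamp`, `sbp`, `dbp`).
#' @param target `"sbp"` or `"dbp"`.
#' @param period optional POSIXct length-2 vector restricting the fit.
#' @return list with `slope` (mmHg/day), `intercept`, `period`, `target`,
#'   `n`.
#' @export
bp_trend_slope <- function(readings, target = c("sbp", "dbp"), period = NULL) {
  target <- match.arg(target)
  if (!is.null(period)) {
    keep <- readings$timestamp >= period[1] & readings$timestamp <= period[2]
    readings <- readings[keep, , drop = FALSE]
  }
  if (nrow(readings) < 2) stop_rfsv("need >= 2 readings in the period")
  days <- (as.numeric(readings$timestamp) -
             as.numeric(readings$timestamp[1])) / 86400
  fit <- lm(readings[[target]] ~ days)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       period = range(readings$timestamp), target = target,
       n = nrow(readings))
}

#' Weekly BP statistics
#'
#' Mean and maximum of the daily mean BP over the first and last 7
#' calendar days covered by the readings, per target.
#'
#' @param readings BP data.frame (`timestamp`, `sbp`, `dbp`).
#' @return nested list: `$sbp`/`$dbp`, each with `first_week` and
#'   `last_week` (`mean`, `max`) and the `change` in both.
#' @export
weekly_bp_stats <- function(readings) {
  if (nrow(readings) < 2) stop_rfsv("need >= 2 readings")
  day <- floor(as.numeric(readings$timestamp) / 86400)
  out <- list()
  for (target in c("sbp", "dbp")) {
    daily <- tapply(readings[[target]], day, mean)
    dd <- as.numeric(names(daily))
    first <- daily[dd < min(dd) + 7]
    last <- daily[dd > max(dd) - 7]
    out[[target]] <- list(
      first_week = list(mean = mean(first), max = max(first)),
      last_week = list(mean = mean(last), max = max(last)),
      change = list(mean = mean(last) - mean(first),
                    max = max(last) - max(first)))
  }
  out
}

# internal: canonical model names of the comparison set
.model_names <- c("SimpleMean", "ARIMA", "RF", "RF-ARIMA", "RFSV")

normalize_model <- function(model) {
  m <- .model_names[match(tolower(gsub("[_ ]", "-", model)),
                          tolower(.model_names))]
  if (any(is.na(m))) {
    stop_rfsv("unknown model(s): ", paste(model[is.na(m)], collapse = ", "),
              " (choose from ", paste(.model_names, collapse = ", "), ")")
  }
  m
}

model_uses_arima <- function(model) model %in% c("ARIMA", "RF-ARIMA", "RFSV")

# internal: fold assignments per repeat; random by default, contiguous
# blocks when chronological
make_folds <- function(n, k, repeats, seed, chronological = FALSE) {
  if (k < 2 || n < k) stop_rfsv("need 2 <= k <= n folds (k = n is leave-one-out)")
  lapply(seq_len(repeats), function(r) {
    if (chronological) {
      sort(rep_len(seq_len(k), n))
    } else {
      set.seed(derive_seed(seed, r))
      sample(rep_len(seq_len(k), n))
    }
  })
}

# internal: fit one model on a training fold and predict the test fold.
# `train`/`test` are imputed feature tables (ARIMA columns attached when
# the model consumes them).
fit_and_predict <- function(model, train, test, target, params, ratio,
                            background_size, base_features) {
  switch(model,
    "SimpleMean" = rep(mean(train[[target]]), nrow(test)),
    "ARIMA" = test[[paste0(toupper(target), "_arima")]],
    "RF" = {
      fit <- train_rf(train, target, params, features = base_features)
      predict(fit, test)
    },
    "RF-ARIMA" = {
      fit <- train_rf(train, target, params)
      predict(fit, test)
    },
    "RFSV" = {
      fit <- train_rfsv(train, target, params, ratio = ratio,
                        background_size = background_size)
      predict(fit, test)
    })
}

#' Repeated k-fold cross-validation of one model
#'
#' Random (non-chronological) splits by default, resampled per repeat.
#' Imputation medians and, for ARIMA-consuming models, the resampled
#' series and selected ARIMA model are computed from the training fold
#' only.  Deterministic given `seed`.
#'
#' @param table a `feature_table` built with `impute = FALSE` (no ARIMA
#'   columns; they are attached fold-wise).
#' @param model one of `"SimpleMean"`, `"ARIMA"`, `"RF"`, `"RF-ARIMA"`,
#'   `"RFSV"`.
#' @param target `"sbp"` or `"dbp"`.
#' @param k folds (default 5).
#' @param repeats repetitions with fresh random splits (default 5).
#' @param seed integer seed.
#' @param params [rf_params()] for the forest models.
#' @param ratio RFSV selection ratio.
#' @param background_size SHAP background cap.
#' @param arima_opts list of arguments for [add_arima_features()]
#'   (`spacing`, `max_p`, ...).
#' @param chronological use contiguous time-ordered folds instead of
#'   random splits.
#' @return list with `metrics` (averaged over repeats), `per_repeat`,
#'   `detail` (per-prediction data.frame), `folds`.
#' @export
cross_validate <- function(table, model = "RF", target = c("sbp", "dbp"),
                           k = 5, repeats = 5, seed = 1,
                           params = rf_params(), ratio = 0.5,
                           background_size = 100, arima_opts = list(),
                           chronological = FALSE) {
  target <- match.arg(target)
  model <- normalize_model(model)
  res <- compare_models(table, targets = target, models = model,
                        horizons = attr(table, "horizon_shift") %||% 0,
                        k = k, repeats = repeats, seed = seed,
                        params = params, ratio = ratio,
                        background_size = background_size,
                        arima_opts = arima_opts,
                        chronological = chronological,
                        tables = list(table))
  per_repeat <- res$per_repeat
  list(metrics = res$metrics[, c("mae", "rmse", "mape", "r2", "n")],
       per_repeat = per_repeat, detail = res$detail, folds = res$folds)
}

#' Compare models across prediction horizons
#'
#' Runs the SimpleMean / ARIMA / RF / RF-ARIMA / RFSV comparison on one
#' subject or a cohort, per target and horizon, with folds shared across
#' models: RF sees no BP-history columns and no selection, RF-ARIMA adds
#' the ARIMA forecast columns, RFSV adds selection on top, and ARIMA uses
#' the forecast column directly as its prediction.  Rows without an ARIMA
#' forecast (insufficient history) are dropped from the fold for all
#' models alike whenever any compared model consumes the forecasts.
#' Paired t-tests compare each model's held-out absolute errors against
#' the reference model (RFSV when present, else the first model).
#'
#' @param datasets a `subject_dataset` or list of them (ignored when
#'   `tables` is given).
#' @param targets subset of `c("sbp", "dbp")`.
#' @param models subset of the five model names.
#' @param horizons prediction horizons in hours (subset of 0/12/24/48).
#' @param k,repeats,seed cross-validation controls.
#' @param params,ratio,background_size forest/RFSV controls.
#' @param arima_opts arguments for [add_arima_features()].
#' @param dedup_policy,min_coverage passed to [build_feature_table()].
#' @param chronological use time-ordered folds.
#' @param tables internal: pre-built unimputed feature tables (one per
#'   subject; overrides feature building, single horizon).
#' @return a `model_comparison`: `metrics` and `per_repeat` data.frames,
#'   `ttests`, `detail`, `folds`, `seed`.
#' @export
compare_models <- function(datasets, targets = c("sbp", "dbp"),
                           models = .model_names, horizons = 0,
                           k = 5, repeats = 5, seed = 1,
                           params = rf_params(), ratio = 0.5,
                           background_size = 100, arima_opts = list(),
                           dedup_policy = "mean",
                           min_coverage = list(hr = 0.5, steps = 0.25),
                           chronological = FALSE, tables = NULL) {
  models <- normalize_model(models)
  targets <- match.arg(targets, c("sbp", "dbp"), several.ok = TRUE)
  if (is.null(tables)) {
    if (inherits(datasets, "subject_dataset")) datasets <- list(datasets)
  } else {
    horizons <- horizons[1]
  }
  n_subj <- if (is.null(tables)) length(datasets) else length(tables)
  any_arima <- any(model_uses_arima(models))
  met_rows <- list(); rep_rows <- list(); det_rows <- list()
  tt_rows <- list(); fold_log <- list()

  for (si in seq_len(n_subj)) {
    for (h in horizons) {
      tab <- if (is.null(tables)) {
        build_feature_table(datasets[[si]], horizon_shift = h,
                            dedup_policy = dedup_policy,
                            min_coverage = min_coverage, impute = FALSE)
      } else tables[[si]]
      sid <- attr(tab, "subject_id")
      n <- nrow(tab)
      folds <- make_folds(n, k, repeats, derive_seed(seed, si * 1000 + h),
                          chronological)
      fold_log[[paste(sid, h, sep = "/")]] <- folds
      # abs-error store: [[target]][[model]] -> vector over (repeat, row)
      errs <- list()
      for (target in targets) errs[[target]] <- lapply(
        setNames(models, models), function(m) numeric(0))
      per_rep_met <- list()

      for (r in seq_len(repeats)) {
        fa <- folds[[r]]
        rep_pred <- list()  # per (target, model): pooled predictions this repeat
        for (fold in seq_len(k)) {
          tr <- which(fa != fold); te <- which(fa == fold)
          medians <- vapply(attr(tab, "feature_names"), function(f) {
            median(tab[[f]][tr], na.rm = TRUE)
          }, numeric(1))
          imp_tab <- impute_features(tab, medians = medians)
          work <- imp_tab
          if (any_arima) {
            fit_readings <- data.frame(timestamp = tab$timestamp[tr],
                                       sbp = tab$sbp[tr], dbp = tab$dbp[tr])
            work <- do.call(add_arima_features,
                            c(list(imp_tab, fit_readings = fit_readings),
                              arima_opts))
            have <- !is.na(work$SBP_arima) & !is.na(work$DBP_arima)
            tr <- tr[have[tr]]; te <- te[have[te]]
            # forecast columns are complete on the retained rows
          }
          if (length(te) == 0 || length(tr) < 20) next
          fparams <- params
          fparams$seed <- derive_seed(params$seed, r * 100 + fold)
          train_t <- work[tr, , drop = FALSE]
          test_t <- work[te, , drop = FALSE]
          for (a in c("subject_id", "feature_names")) {
            attr(train_t, a) <- attr(work, a); attr(test_t, a) <- attr(work, a)
          }
          base_features <- setdiff(attr(work, "feature_names"),
                                   c("SBP_arima", "DBP_arima"))
          for (target in targets) {
            for (m in models) {
              pred <- fit_and_predict(m, train_t, test_t, target, fparams,
                                      ratio, background_size, base_features)
              actual <- test_t[[target]]
              chunk <- data.frame(
                subject = sid, horizon = h, target = target, model = m,
                repetition = r, fold = fold, row = te,
                actual = actual, predicted = pred)
              det_rows[[length(det_rows) + 1]] <- chunk
              key <- paste(target, m, sep = "\r")
              rep_pred[[key]] <- rbind(rep_pred[[key]], chunk)
              errs[[target]][[m]] <- c(errs[[target]][[m]],
                                       abs(pred - actual))
            }
          }
        }
        # per-repeat pooled metrics
        for (target in targets) for (m in models) {
          dd <- rep_pred[[paste(target, m, sep = "\r")]]
          if (is.null(dd)) next
          mm <- compute_metrics(dd$predicted, dd$actual)
          per_rep_met[[length(per_rep_met) + 1]] <- data.frame(
            subject = sid, horizon = h, target = target, model = m,
            repetition = r, mae = mm$mae, rmse = mm$rmse, mape = mm$mape,
            r2 = mm$r2, n = mm$n)
        }
      }
      prm <- do.call(rbind, per_rep_met)
      rep_rows[[length(rep_rows) + 1]] <- prm
      for (target in targets) for (m in models) {
        sub <- prm[prm$target == target & prm$model == m, , drop = FALSE]
        if (nrow(sub) == 0) next
        met_rows[[length(met_rows) + 1]] <- data.frame(
          subject = sid, horizon = h, target = target, model = m,
          mae = mean(sub$mae), rmse = mean(sub$rmse), mape = mean(sub$mape),
          r2 = mean(sub$r2), n = round(mean(sub$n)))
      }
      ref <- if ("RFSV" %in% models) "RFSV" else models[1]
      for (target in targets) for (m in setdiff(models, ref)) {
        ea <- errs[[target]][[ref]]; eb <- errs[[target]][[m]]
        if (length(ea) >= 3 && length(ea) == length(eb)) {
          tt <- paired_ttest(ea, eb)
          tt_rows[[length(tt_rows) + 1]] <- data.frame(
            subject = sid, horizon = h, target = target,
            model_a = ref, model_b = m, statistic = tt$statistic,
            p_value = tt$p_value, degenerate = tt$degenerate)
        }
      }
    }
  }
  structure(list(metrics = do.call(rbind, met_rows),
                 per_repeat = do.call(rbind, rep_rows),
                 ttests = if (length(tt_rows)) do.call(rbind, tt_rows) else NULL,
                 detail = do.call(rbind, det_rows),
                 folds = fold_log, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}
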