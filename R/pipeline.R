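# End-to-end orchestration: simulate -> featurize -> arima -> train ->
# evaluate -> recommend, driven by one declarative configuration with a
# single global seed fanned out to stage seeds, writing intermediate
# artifacts and a manifest with content hashes.

#' Default run configuration
#'
#' Field defaults follow the emulated study protocol: 500 trees, per-split
#' feature fraction 0.33, minimum split size 2, selection ratio 0.5,
#' 5-fold cross-validation with 5 repeats, 12-hour resampling grid
#' (seasonal period = 1 day).
#'
#' @param out_dir output directory for artifacts.
#' @param seed global run seed.
#' @return a nested configuration list.
#' @export
default_config <- function(out_dir = "rfsv_run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(n_subjects = 3, days = 90, age = 50,
                    missing_bp_rate = 0.1, heterogeneity = 0.4),
    features = list(horizon = 0, dedup_policy = "mean",
                    min_coverage = list(hr = 0.5, steps = 0.25)),
    arima = list(spacing = 12, max_p = 2, max_q = 1, max_d = 1,
                 seasonal = FALSE),
    rf = list(n_trees = 500, feature_ratio_per_tree = 0.33,
              min_samples_split = 2),
    selection = list(ratio = 0.5, background_size = 100),
    evaluate = list(models = c("SimpleMean", "ARIMA", "RF", "RF-ARIMA", "RFSV"),
                    targets = c("sbp", "dbp"), folds = 5, repeats = 5),
    recommend = list(top_n = 3, direction_threshold = 0.2))
}

#' Load a YAML run configuration
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_rfsv("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

validate_config <- function(config) {
  if (config$evaluate$folds < 2) stop_rfsv("config: evaluate$folds must be >= 2")
  if (config$selection$ratio <= 0 || config$selection$ratio > 1) {
    stop_rfsv("config: selection$ratio must be in (0, 1]")
  }
  if (!config$features$horizon %in% c(0, 12, 24, 48)) {
    stop_rfsv("config: features$horizon must be one of 0, 12, 24, 48")
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes simulate, featurize, ARIMA augmentation, RFSV training,
#' model comparison and recommendation generation in order, writing each
#' stage's artifacts under `config$out_dir` and a `manifest.json`
#' recording the configuration, derived stage seeds and MD5 hashes of all
#' written files.  Deterministic stages reproduce bit-identical artifacts
#' under the same configuration and seed.
#'
#' @param config configuration list from [default_config()] or
#'   [load_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- character(0)
  add_art <- function(p) artifacts <<- c(artifacts, p)

  ## stage 1: simulate
  rfsv_log("info", "stage simulate: ", config$simulate$n_subjects, " subject(s)")
  prof <- sim_profile(age = config$simulate$age, days = config$simulate$days,
                      missing_bp_rate = config$simulate$missing_bp_rate)
  cohort <- simulate_cohort(config$simulate$n_subjects, prof,
                            seed = derive_seed(seed, 1),
                            heterogeneity = config$simulate$heterogeneity)
  for (i in seq_along(cohort)) {
    ds <- cohort[[i]]$dataset
    base <- file.path(out, ds$subject_id)
    write_subject_dataset(ds, paste0(base, "_wearable.csv"),
                          paste0(base, "_sleep.csv"), paste0(base, "_bp.csv"))
    truth <- cohort[[i]]$truth
    gt <- do.call(rbind, lapply(truth$effects, function(ef) {
      data.frame(feature_name = ef$feature_name, coefficient = ef$coefficient,
                 target = ef$applies_to)
    }))
    write.csv(gt, paste0(base, "_ground_truth.csv"), row.names = FALSE)
    add_art(paste0(base, c("_wearable.csv", "_sleep.csv", "_bp.csv",
                           "_ground_truth.csv")))
  }

  ## stage 2+3: featurize and attach ARIMA columns
  rfsv_log("info", "stage featurize: horizon ", config$features$horizon, " h")
  ar <- config$arima
  tables <- lapply(cohort, function(su) {
    tab <- build_feature_table(su$dataset,
                               horizon_shift = config$features$horizon,
                               dedup_policy = config$features$dedup_policy,
                               min_coverage = config$features$min_coverage)
    add_arima_features(tab, spacing = ar$spacing, max_p = ar$max_p,
                       max_q = ar$max_q, max_d = ar$max_d,
                       seasonal = isTRUE(ar$seasonal))
  })
  for (tab in tables) {
    p <- file.path(out, paste0(attr(tab, "subject_id"), "_features.csv"))
    write_feature_table(tab, p)
    add_art(p)
  }

  ## stage 4: train RFSV per subject and target
  rfsv_log("info", "stage train: RFSV per subject")
  models <- list()
  imp_rows <- list()
  for (tab in tables) {
    sid <- attr(tab, "subject_id")
    # drop rows without forecast history, then model on complete rows
    keep <- !is.na(tab$SBP_arima) & !is.na(tab$DBP_arima)
    tt <- tab[keep, , drop = FALSE]
    for (a in c("subject_id", "feature_names")) attr(tt, a) <- attr(tab, a)
    for (target in config$evaluate$targets) {
      params <- rf_params(n_trees = config$rf$n_trees,
                          feature_ratio_per_tree = config$rf$feature_ratio_per_tree,
                          min_samples_split = config$rf$min_samples_split,
                          seed = derive_seed(seed, 2))
      fit <- train_rfsv(tt, target, params,
                        ratio = config$selection$ratio,
                        background_size = config$selection$background_size)
      models[[paste(sid, target, sep = "/")]] <- list(model = fit, table = tt)
      imp <- sort(fit$importance$mean_abs, decreasing = TRUE)
      imp_rows[[length(imp_rows) + 1]] <- data.frame(
        subject = sid, target = target, feature = names(imp),
        mean_abs_shap = unname(imp),
        selected = names(imp) %in% fit$selected)
    }
  }
  imp_path <- file.path(out, "importance.csv")
  write.csv(do.call(rbind, imp_rows), imp_path, row.names = FALSE)
  add_art(imp_path)

  ## stage 5: model comparison
  rfsv_log("info", "stage evaluate: ", paste(config$evaluate$models, collapse = ", "))
  comp <- compare_models(
    lapply(cohort, `[[`, "dataset"),
    targets = config$evaluate$targets, models = config$evaluate$models,
    horizons = config$features$horizon, k = config$evaluate$folds,
    repeats = config$evaluate$repeats, seed = derive_seed(seed, 3),
    params = rf_params(n_trees = config$rf$n_trees,
                       feature_ratio_per_tree = config$rf$feature_ratio_per_tree,
                       min_samples_split = config$rf$min_samples_split,
                       seed = derive_seed(seed, 3)),
    ratio = config$selection$ratio,
    background_size = config$selection$background_size,
    arima_opts = list(spacing = ar$spacing, max_p = ar$max_p,
                      max_q = ar$max_q, max_d = ar$max_d,
                      seasonal = isTRUE(ar$seasonal)),
    dedup_policy = config$features$dedup_policy,
    min_coverage = config$features$min_coverage)
  cmp_path <- file.path(out, "comparison.csv")
  write.csv(comp$metrics, cmp_path, row.names = FALSE)
  add_art(cmp_path)
  if (!is.null(comp$ttests)) {
    tt_path <- file.path(out, "ttests.csv")
    write.csv(comp$ttests, tt_path, row.names = FALSE)
    add_art(tt_path)
  }

  ## stage 6: recommendations
  rfsv_log("info", "stage recommend: top ", config$recommend$top_n, " factors")
  rec_rows <- list()
  for (key in names(models)) {
    entry <- models[[key]]
    rep <- generate_recommendations(entry$model, entry$table,
                                    top_n = config$recommend$top_n,
                                    threshold = config$recommend$direction_threshold)
    if (!is.null(rep$recommendations)) {
      rr <- rep$recommendations
      rr$subject <- rep$subject_id
      rr$target <- rep$target
      rec_rows[[length(rec_rows) + 1]] <- rr
    }
  }
  rec_path <- file.path(out, "recommendations.csv")
  write.csv(do.call(rbind, rec_rows), rec_path, row.names = FALSE)
  add_art(rec_path)

  ## manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("rfsv")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1),
                       train = derive_seed(seed, 2),
                       evaluate = derive_seed(seed, 3)),
    config = config,
    artifacts = lapply(setNames(artifacts, basename(artifacts)), function(p) {
      list(md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rfsv_log("info", "pipeline complete: ", length(artifacts), " artifacts in ", out)
  invisible(manifest)
}
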