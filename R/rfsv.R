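# Random-forest modeling and the RFSV pipeline: train on all features,
# rank by mean absolute Shapley value, keep the top fraction, retrain.

#' Random-forest hyperparameters
#'
#' Defaults follow the study protocol: 500 trees, per-split candidate
#' fraction 0.33 of the features, minimum node size to split of 2.
#'
#' @param n_trees number of trees.
#' @param feature_ratio_per_tree fraction of features tried at each split.
#' @param min_samples_split minimum samples a node needs to be split.
#' @param seed integer seed for the forest.
#' @return an `rf_params` list.
#' @export
rf_params <- function(n_trees = 500, feature_ratio_per_tree = 0.33,
                      min_samples_split = 2, seed = 1) {
  stopifnot(n_trees >= 1, feature_ratio_per_tree > 0,
            feature_ratio_per_tree <= 1, min_samples_split >= 2)
  structure(list(n_trees = as.integer(n_trees),
                 feature_ratio_per_tree = feature_ratio_per_tree,
                 min_samples_split = as.integer(min_samples_split),
                 seed = as.integer(seed)),
            class = "rf_params")
}

# internal: extract the feature matrix for modeling
feature_matrix <- function(table, features) {
  miss <- setdiff(features, names(table))
  if (length(miss)) {
    stop_rfsv("table lacks feature column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(as.data.frame(table)[features])
  storage.mode(m) <- "double"
  m
}

#' Train a random-forest regression model
#'
#' Bootstrap-aggregated regression trees with per-split feature
#' subsampling, via \pkg{ranger}; deterministic given `params$seed`.
#'
#' @param table a `feature_table` (imputed; no missing feature cells).
#' @param target `"sbp"` or `"dbp"`.
#' @param params an [rf_params()].
#' @param features optional subset of feature names to train on (defaults
#'   to all features in the table).
#' @return an `rf_model`.
#' @export
train_rf <- function(table, target = c("sbp", "dbp"), params = rf_params(),
                     features = NULL) {
  target <- match.arg(target)
  features <- features %||% attr(table, "feature_names")
  x <- feature_matrix(table, features)
  y <- as.numeric(table[[target]])
  ok <- complete.cases(x) & is.finite(y)
  if (!all(ok)) {
    stop_rfsv("non-finite cells in ", sum(!ok),
              " row(s) after imputation; impute before training")
  }
  if (nrow(x) < 20) stop_rfsv("need >= 20 complete rows to train, got ", nrow(x))
  df <- as.data.frame(x)
  df$..y <- y
  forest <- ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = params$n_trees,
    mtry = max(1L, as.integer(ceiling(params$feature_ratio_per_tree *
                                        length(features)))),
    min.node.size = params$min_samples_split,
    importance = "impurity",
    seed = params$seed, num.threads = 1)
  structure(list(forest = forest, feature_names = features, target = target,
                 params = params), class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> target %s; %d trees on %d features\n",
              x$target, x$params$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Predict from an `rf_model` or `rfsv_model`
#'
#' Forest-average predictions; an `rfsv_model` predicts with its final
#' (post-selection) forest.
#'
#' @param object the model.
#' @param rows a `feature_table` or data.frame holding the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric predictions (mmHg), one per row.
#' @export
predict.rf_model <- function(object, rows, ...) {
  x <- feature_matrix(rows, object$feature_names)
  if (any(!is.finite(x))) stop_rfsv("prediction rows contain non-finite cells")
  as.numeric(predict(object$forest, data = as.data.frame(x),
                     num.threads = 1)$predictions)
}

# internal: convert a ranger forest into plain node matrices for the C++
# Shapley kernel (columns: left, right, var, split, pred; -1 sentinels).
# ranger sends x[var] <= splitval to the left child.
forest_matrices <- function(model) {
  stopifnot(inherits(model, "rf_model"))
  lapply(seq_len(model$params$n_trees), function(t) {
    ti <- ranger::treeInfo(model$forest, tree = t)
    cbind(left = ifelse(is.na(ti$leftChild), -1, ti$leftChild),
          right = ifelse(is.na(ti$rightChild), -1, ti$rightChild),
          var = ifelse(is.na(ti$splitvarID), -1, ti$splitvarID),
          split = ifelse(is.na(ti$splitval), 0, ti$splitval),
          pred = ifelse(is.na(ti$prediction), 0, ti$prediction))
  })
}

#' Shapley-value feature importance (interventional Tree SHAP)
#'
#' Per-sample Shapley values of the forest's predictions, with feature
#' removal defined by marginal expectation over a background sample of
#' training rows: phi[j, k] is feature k's contribution (mmHg) to sample
#' j's prediction relative to the baseline (mean background prediction).
#' Mean absolute importance is the per-feature average of |phi| over
#' samples.  Every row satisfies `baseline + sum(phi) = prediction`.
#'
#' @param model an `rf_model`.
#' @param table the `feature_table` holding the samples to explain.
#' @param background optional explicit background rows (data.frame); by
#'   default the training rows, subsampled to `background_size`.
#' @param background_size cap on the background sample (default 100).
#' @param seed seed for the background subsample.
#' @return an `importance_report` with elements `phi` (J x K matrix),
#'   `mean_abs`, `baseline`, `method = "shap"`.
#' @export
shap_importance <- function(model, table, background = NULL,
                            background_size = 100, seed = 1) {
  stopifnot(inherits(model, "rf_model"))
  X <- feature_matrix(table, model$feature_names)
  if (is.null(background)) {
    Z <- X
    if (nrow(Z) > background_size) {
      set.seed(seed)
      Z <- Z[sort(sample.int(nrow(Z), background_size)), , drop = FALSE]
    }
  } else {
    Z <- feature_matrix(background, model$feature_names)
  }
  if (nrow(Z) == 0) stop_rfsv("background sample is empty")
  res <- treeshap_interventional_cpp(forest_matrices(model), X, Z)
  phi <- res$phi
  colnames(phi) <- model$feature_names
  # efficiency guard: baseline + sum(phi) must reproduce the prediction
  pred <- predict(model, table)
  dev <- max(abs(res$baseline + rowSums(phi) - pred))
  if (dev > 1e-6) {
    rfsv_log("warn", "SHAP efficiency deviation ", format(dev),
             " exceeds 1e-6; tree traversal may be inconsistent")
  }
  structure(list(phi = phi,
                 mean_abs = colMeans(abs(phi)),
                 baseline = res$baseline,
                 method = "shap",
                 target = model$target),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report method=%s> %d features\n",
              x$method, length(x$mean_abs)))
  top <- sort(x$mean_abs, decreasing = TRUE)
  print(round(head(top, 5), 4))
  invisible(x)
}

#' Select the top features by importance
#'
#' Keeps the `ceiling(ratio * K)` features with the largest mean absolute
#' importance; ties are broken by the stable feature order of the report.
#'
#' @param report an `importance_report`.
#' @param ratio selection ratio in (0, 1].
#' @return character vector of selected feature names.
#' @export
select_features <- function(report, ratio = 0.5) {
  stopifnot(inherits(report, "importance_report"), ratio > 0, ratio <= 1)
  imp <- report$mean_abs
  k <- ceiling(ratio * length(imp))
  ord <- order(-imp, seq_along(imp))  # stable: earlier feature wins ties
  names(imp)[ord[seq_len(k)]]
}

#' Train the RFSV pipeline
#'
#' Train a forest on all features, compute Shapley importance, keep the
#' top `ratio` of features, retrain on the selected features.  All stages
#' are recorded in the returned object.
#'
#' @param table imputed `feature_table` (ARIMA columns attached if wanted).
#' @param target `"sbp"` or `"dbp"`.
#' @param params an [rf_params()].
#' @param ratio selection ratio (default 0.5).
#' @param background_size background cap for [shap_importance()].
#' @return an `rfsv_model` with elements `pre_model`, `importance`,
#'   `selected`, `final_model`, `ratio`, `target`.
#' @export
train_rfsv <- function(table, target = c("sbp", "dbp"), params = rf_params(),
                       ratio = 0.5, background_size = 100) {
  target <- match.arg(target)
  pre <- train_rf(table, target, params)
  imp <- shap_importance(pre, table, background_size = background_size,
                         seed = params$seed)
  selected <- select_features(imp, ratio)
  # keep the pre-model's column order so ratio = 1 reproduces it exactly
  selected <- pre$feature_names[pre$feature_names %in% selected]
  final <- train_rf(table, target, params, features = selected)
  structure(list(pre_model = pre, importance = imp, selected = selected,
                 final_model = final, ratio = ratio, target = target,
                 params = params),
            class = "rfsv_model")
}

#' @export
print.rfsv_model <- function(x, ...) {
  cat(sprintf("<rfsv_model> target %s; %d of %d features selected (ratio %.2f)\n",
              x$target, length(x$selected),
              length(x$pre_model$feature_names), x$ratio))
  invisible(x)
}

#' @rdname predict.rf_model
#' @export
predict.rfsv_model <- function(object, rows, ...) {
  predict(object$final_model, rows)
}

# internal: mutual information between two numeric vectors after quantile
# binning (used by the information-gain importance scorer)
mutual_information <- function(x, y, bins = 10) {
  qb <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1),
                          na.rm = TRUE))
    if (length(br) < 2) return(rep(1L, length(v)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  bx <- qb(x); by <- qb(y)
  ok <- !is.na(bx) & !is.na(by)
  if (!any(ok)) return(0)
  tab <- table(bx[ok], by[ok])
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Alternative feature-importance scorers
#'
#' The three comparison scorers: absolute Pearson correlation with the
#' target, mutual information after 10-quantile binning (information
#' gain), and the forest's mean-decrease-impurity importance.  These give
#' a ranking only; no per-sample attribution matrix.
#'
#' @param method `"pearson"`, `"info_gain"` or `"impurity"`.
#' @param table imputed `feature_table`.
#' @param target `"sbp"` or `"dbp"`.
#' @param model a trained `rf_model`; required for `"impurity"`.
#' @param bins quantile bins for `"info_gain"`.
#' @return an `importance_report` with `phi = NULL`.
#' @export
alt_importance <- function(method = c("pearson", "info_gain", "impurity"),
                           table, target = c("sbp", "dbp"), model = NULL,
                           bins = 10) {
  method <- match.arg(method)
  target <- match.arg(target)
  features <- attr(table, "feature_names")
  y <- as.numeric(table[[target]])
  imp <- setNames(numeric(length(features)), features)
  if (method == "impurity") {
    if (is.null(model)) stop_rfsv("impurity importance needs a trained rf_model")
    vi <- model$forest$variable.importance
    imp[names(vi)] <- vi
  } else {
    for (f in features) {
      v <- as.numeric(table[[f]])
      if (length(unique(v[!is.na(v)])) < 2) {
        rfsv_log("debug", "zero-variance feature ", f, ": importance 0")
        next
      }
      imp[[f]] <- if (method == "pearson") {
        abs(cor(v, y, use = "complete.obs"))
      } else {
        mutual_information(v, y, bins = bins)
      }
    }
  }
  structure(list(phi = NULL, mean_abs = imp, baseline = mean(y),
                 method = method, target = target),
            class = "importance_report")
}
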