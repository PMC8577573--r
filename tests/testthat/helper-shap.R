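# Brute-force Shapley values with marginal (interventional) expectations:
# enumerates every feature subset and evaluates the coalition value as the
# mean model prediction over the background with out-of-coalition features
# replaced by background values.  Uses the forest's own predict path, so it
# is independent of the tree-walking SHAP kernel.
brute_shap <- function(model, X, Z) {
  feats <- model$feature_names
  p <- length(feats)
  subsets <- lapply(0:(2^p - 1), function(mask) feats[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0])
  out <- matrix(0, nrow(X), p, dimnames = list(NULL, feats))
  for (j in seq_len(nrow(X))) {
    x <- X[j, ]
    # memoise f(S) over all subsets
    fS <- vapply(subsets, function(S) {
      Zm <- Z
      for (f in S) Zm[, f] <- x[[f]]
      mean(predict(model$forest, data = as.data.frame(Zm),
                   num.threads = 1)$predictions)
    }, numeric(1))
    key <- function(S) paste0("s", paste(sort(match(S, feats)), collapse = "-"))
    fS2 <- setNames(fS, vapply(subsets, key, character(1)))
    for (k in feats) {
      rest <- setdiff(feats, k)
      for (sz in 0:length(rest)) {
        combs <- if (sz == 0) list(character(0)) else
          asplit(utils::combn(rest, sz), 2)
        w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
        for (S in combs) {
          out[j, k] <- out[j, k] +
            w * (fS2[[key(c(S, k))]] - fS2[[key(S)]])
        }
      }
    }
  }
  out
}
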