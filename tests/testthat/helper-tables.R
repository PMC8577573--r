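# shared fixtures, all built in code

options(rfsv.log_level = "error")

# wrap a plain data.frame (with timestamp/sbp/dbp columns) as a feature_table
wrap_table <- function(df, subject_id = "T") {
  fn <- setdiff(names(df), c("timestamp", "sbp", "dbp"))
  rfsv:::as_feature_table(df, subject_id = subject_id, feature_names = fn)
}

# iid-feature regression table: k features, the first n_causal carry linear
# effects (betas), the rest are pure noise
toy_table <- function(n = 120, k = 10, n_causal = 3,
                      betas = c(5, -4, 3), noise_sd = 1, seed = 1,
                      base = 120) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, sprintf("f%02d", seq_len(k))))
  y <- base + as.numeric(x[, seq_len(n_causal), drop = FALSE] %*%
                           betas[seq_len(n_causal)]) + rnorm(n, 0, noise_sd)
  df <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
                     43200 * seq_len(n), x)
  df$sbp <- y
  df$dbp <- y - 45
  list(table = wrap_table(df), causal = colnames(x)[seq_len(n_causal)],
       betas = betas[seq_len(n_causal)])
}

# hand-built subject dataset: constant channels over `hours` hours of
# minute records, one sleep session per night (23:00-07:00, light), BP
# readings supplied by the caller
constant_dataset <- function(hours = 96, steps = 100, hr = 60, speed = 5,
                             floors = 0, bp_times = NULL, sbp = 120, dbp = 80,
                             age = 40, origin = "2024-03-01") {
  o <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  mt <- o + seq(0, hours * 3600 - 60, by = 60)
  minutes <- data.frame(timestamp = mt, heart_rate = hr, steps = steps,
                        speed = speed, floors = floors)
  nights <- seq_len(max(1, floor(hours / 24)))
  sleep <- data.frame(
    start = o + (nights - 1) * 86400 + 23 * 3600,
    end = o + (nights - 1) * 86400 + 31 * 3600,
    stage = "light")
  sleep <- sleep[sleep$end <= max(mt) + 60, , drop = FALSE]
  if (nrow(sleep) == 0) sleep <- sleep[0, ]
  if (is.null(bp_times)) bp_times <- max(mt) + 60
  bp <- data.frame(timestamp = bp_times,
                   sbp = rep_len(sbp, length(bp_times)),
                   dbp = rep_len(dbp, length(bp_times)))
  subject_dataset("CONST", age, minutes, sleep, bp)
}

# memoised simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}
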