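#' @keywords internal
"_PACKAGE"

#' @useDynLib rfsv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats arima predict median sd cor var quantile rnorm runif
#'   rpois rbinom lm coef pt qt AIC logLik complete.cases setNames approx
#'   residuals t.test
#' @importFrom utils read.csv write.csv head tail
NULL

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Structured logging to stderr
#'
#' Emits a timestamped log line when `level` is at or above the threshold in
#' `options(rfsv.log_level = )` (default `"info"`).
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... message parts, pasted together.
#' @return invisibly, the message string.
#' @export
rfsv_log <- function(level = "info", ...) {
  level <- match.arg(level, names(.log_levels))
  thr <- getOption("rfsv.log_level", "info")
  msg <- paste0(...)
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[%s] %s rfsv: %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), msg))
  }
  invisible(msg)
}

#' Derive a child seed from a run seed
#'
#' Deterministic fan-out of one global seed into per-stage / per-subject
#' seeds, kept within the 32-bit integer range.
#'
#' @param seed integer run seed.
#' @param index non-negative integer stream index (stage or subject number).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 0)
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729 + 13) %%
               2147483647)
}

# internal: parse ISO-8601 timestamps with explicit offset to POSIXct (UTC)
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  # fall back to space-separated / offset-free forms
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(x[bad], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%d %H:%M"))
  }
  out
}

# internal: format POSIXct as ISO-8601 UTC with explicit offset
format_timestamp <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")
}

# internal: decimal clock hour in [0, 24)
clock_hour <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# count of elements of sorted vector v that are <= x (scalar binary search;
# unlike findInterval it does not re-validate v on every call)
bsearch_le <- function(x, v) {
  lo <- 0L; hi <- length(v)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

stop_rfsv <- function(..., class = "rfsv_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
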