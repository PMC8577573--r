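# Readers/writers for the three delimited input tables (wearable minutes,
# sleep sessions, BP readings), the feature-table artifact, and the
# subject_dataset container.  Dialect: comma separator, dot decimal,
# ISO-8601 timestamps with explicit offset; missing numeric cells are empty
# strings on disk and NA in memory.

#' Construct a subject dataset
#'
#' Bundles one subject's minute-level wearable stream, sleep sessions and
#' blood-pressure readings with the subject's age.  All components are
#' validated and sorted ascending by time; duplicate wearable timestamps are
#' collapsed by keeping the last occurrence (a later sync overwrites an
#' earlier partial record).
#'
#' @param subject_id opaque subject identifier.
#' @param age age in years, in `[18, 120]`.
#' @param minutes data.frame with columns `timestamp` (POSIXct),
#'   `heart_rate`, `steps`, `speed`, `floors` (numeric, NA allowed).
#' @param sleep data.frame with columns `start`, `end` (POSIXct), `stage`
#'   (one of `"light"`, `"rem"`, `"deep"`).
#' @param bp data.frame with columns `timestamp` (POSIXct), `sbp`, `dbp`
#'   (mmHg).
#' @return an object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, age, minutes, sleep, bp) {
  if (!is.numeric(age) || length(age) != 1 || is.na(age) ||
      age < 18 || age > 120) {
    stop_rfsv("age must be a single number in [18, 120], got ", age)
  }
  minutes <- validate_minutes(minutes)
  sleep <- validate_sleep(sleep)
  bp <- validate_bp(bp)
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 minutes = minutes, sleep = sleep, bp = bp),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset '%s'> age %g; %d minute records, %d sleep sessions, %d BP readings\n",
              x$subject_id, x$age, nrow(x$minutes), nrow(x$sleep), nrow(x$bp)))
  if (nrow(x$bp) > 0) {
    cat(sprintf("  BP span: %s .. %s\n",
                format_timestamp(min(x$bp$timestamp)),
                format_timestamp(max(x$bp$timestamp))))
  }
  invisible(x)
}

validate_minutes <- function(minutes) {
  need <- c("timestamp", "heart_rate", "steps", "speed", "floors")
  missing_cols <- setdiff(need, names(minutes))
  if (length(missing_cols)) {
    stop_rfsv("wearable table lacks columns: ",
              paste(missing_cols, collapse = ", "))
  }
  minutes <- as.data.frame(minutes)[need]
  if (!inherits(minutes$timestamp, "POSIXct")) {
    minutes$timestamp <- parse_timestamp(minutes$timestamp)
  }
  bad <- is.na(minutes$timestamp)
  if (any(bad)) {
    rfsv_log("warn", sum(bad), " wearable rows with unparseable timestamps dropped")
    minutes <- minutes[!bad, , drop = FALSE]
  }
  for (col in c("heart_rate", "steps", "speed", "floors")) {
    minutes[[col]] <- as.numeric(minutes[[col]])
    neg <- !is.na(minutes[[col]]) & minutes[[col]] < 0
    if (any(neg)) {
      rfsv_log("warn", sum(neg), " negative ", col, " values set to NA")
      minutes[[col]][neg] <- NA_real_
    }
  }
  implaus <- !is.na(minutes$heart_rate) & minutes$heart_rate >= 300
  if (any(implaus)) {
    rfsv_log("warn", sum(implaus), " heart_rate values >= 300 set to NA")
    minutes$heart_rate[implaus] <- NA_real_
  }
  ord <- order(minutes$timestamp)
  minutes <- minutes[ord, , drop = FALSE]
  # duplicate timestamps: keep last occurrence
  dup <- duplicated(minutes$timestamp, fromLast = TRUE)
  if (any(dup)) {
    rfsv_log("info", sum(dup), " duplicate wearable timestamps collapsed (kept last)")
    minutes <- minutes[!dup, , drop = FALSE]
  }
  rownames(minutes) <- NULL
  minutes
}

validate_sleep <- function(sleep) {
  need <- c("start", "end", "stage")
  if (!all(need %in% names(sleep))) {
    stop_rfsv("sleep table must have columns start, end, stage")
  }
  sleep <- as.data.frame(sleep)[need]
  if (!inherits(sleep$start, "POSIXct")) sleep$start <- parse_timestamp(sleep$start)
  if (!inherits(sleep$end, "POSIXct")) sleep$end <- parse_timestamp(sleep$end)
  sleep$stage <- as.character(sleep$stage)
  bad_stage <- !sleep$stage %in% c("light", "rem", "deep")
  if (any(bad_stage)) {
    stop_rfsv("unknown sleep stage(s): ",
              paste(unique(sleep$stage[bad_stage]), collapse = ", "))
  }
  if (any(is.na(sleep$start) | is.na(sleep$end))) {
    stop_rfsv("sleep table has unparseable start/end timestamps")
  }
  if (any(sleep$end <= sleep$start)) {
    stop_rfsv("sleep sessions must have end > start")
  }
  sleep <- sleep[order(sleep$start), , drop = FALSE]
  rownames(sleep) <- NULL
  sleep
}

validate_bp <- function(bp) {
  need <- c("timestamp", "sbp", "dbp")
  if (!all(need %in% names(bp))) {
    stop_rfsv("bp table must have columns timestamp, sbp, dbp")
  }
  bp <- as.data.frame(bp)[need]
  if (!inherits(bp$timestamp, "POSIXct")) bp$timestamp <- parse_timestamp(bp$timestamp)
  bp$sbp <- as.numeric(bp$sbp)
  bp$dbp <- as.numeric(bp$dbp)
  if (nrow(bp) == 0) stop_rfsv("BP table is empty")
  if (any(is.na(bp$timestamp))) stop_rfsv("bp table has unparseable timestamps")
  bad <- which(!(bp$sbp > bp$dbp & bp$dbp > 0))
  if (length(bad)) {
    stop_rfsv("BP invariant sbp > dbp > 0 violated at row(s) ",
              paste(bad, collapse = ", "),
              " (e.g. sbp=", bp$sbp[bad[1]], ", dbp=", bp$dbp[bad[1]], ")")
  }
  bp <- bp[order(bp$timestamp), , drop = FALSE]
  dup <- duplicated(bp$timestamp, fromLast = TRUE)
  if (any(dup)) {
    rfsv_log("info", sum(dup), " duplicate BP timestamps collapsed (kept last)")
    bp <- bp[!dup, , drop = FALSE]
  }
  rownames(bp) <- NULL
  bp
}

#' Load a subject dataset from three delimited files
#'
#' Reads the wearable minute table (`timestamp, heart_rate, steps, speed,
#' floors`), the sleep-session table (`start, end, stage`) and the BP table
#' (`timestamp, sbp, dbp`), validates and sorts them, and bundles them into
#' a [subject_dataset()].  Malformed rows are counted and reported via
#' [rfsv_log()].
#'
#' @param wearable_path,sleep_path,bp_path paths to the three CSV files.
#' @param age subject age in years.
#' @param subject_id subject identifier (defaults to the BP file stem).
#' @return a `subject_dataset`.
#' @export
load_subject_dataset <- function(wearable_path, sleep_path, bp_path, age,
                                 subject_id = NULL) {
  for (p in c(wearable_path, sleep_path, bp_path)) {
    if (!file.exists(p)) stop_rfsv("input file not found: ", p)
  }
  minutes <- read.csv(wearable_path, stringsAsFactors = FALSE,
                      na.strings = c("", "NA"))
  sleep <- read.csv(sleep_path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  bp <- read.csv(bp_path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(bp) == 0) stop_rfsv("BP file is empty: ", bp_path)
  subject_dataset(subject_id %||% sub("\\.[^.]*$", "", basename(bp_path)),
                  age = age, minutes = minutes, sleep = sleep, bp = bp)
}

#' Write a subject dataset to three delimited files
#'
#' Inverse of [load_subject_dataset()]; writes the wearable, sleep and BP
#' tables in the package's delimited dialect.
#'
#' @param dataset a `subject_dataset`.
#' @param wearable_path,sleep_path,bp_path output paths.
#' @return invisibly, the dataset.
#' @export
write_subject_dataset <- function(dataset, wearable_path, sleep_path, bp_path) {
  stopifnot(inherits(dataset, "subject_dataset"))
  m <- dataset$minutes
  m$timestamp <- format_timestamp(m$timestamp)
  write.csv(m, wearable_path, row.names = FALSE, na = "", quote = FALSE)
  s <- dataset$sleep
  s$start <- format_timestamp(s$start)
  s$end <- format_timestamp(s$end)
  write.csv(s, sleep_path, row.names = FALSE, na = "", quote = FALSE)
  b <- dataset$bp
  b$timestamp <- format_timestamp(b$timestamp)
  write.csv(b, bp_path, row.names = FALSE, na = "", quote = FALSE)
  invisible(dataset)
}

#' Write a feature table to disk
#'
#' One row per retained BP reading; columns are `timestamp`, the engineered
#' feature names, and the targets `sbp`, `dbp`.  The subject id travels in a
#' `# subject_id=` comment header.  Missing cells are written as empty
#' strings.
#'
#' @param table a `feature_table` (see [build_feature_table()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) == 0) stop_rfsv("refusing to write an empty feature table")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_rfsv("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s", attr(table, "subject_id") %||% "unknown"),
             con)
  out <- as.data.frame(table)
  out$timestamp <- format_timestamp(out$timestamp)
  write.csv(out, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input path.
#' @return a `feature_table` data.frame with attributes `subject_id` and
#'   `feature_names`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_rfsv("feature table not found: ", path)
  first <- readLines(path, n = 1)
  subject_id <- if (grepl("^# subject_id=", first)) {
    sub("^# subject_id=", "", first)
  } else "unknown"
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 na.strings = c("", "NA"))
  df$timestamp <- parse_timestamp(df$timestamp)
  feature_names <- setdiff(names(df), c("timestamp", "sbp", "dbp"))
  as_feature_table(df, subject_id = subject_id, feature_names = feature_names)
}

# internal: stamp the feature_table class and attributes onto a data.frame
as_feature_table <- function(df, subject_id, feature_names) {
  stopifnot(all(c("timestamp", "sbp", "dbp") %in% names(df)))
  df <- df[c("timestamp", feature_names, "sbp", "dbp")]
  attr(df, "subject_id") <- subject_id
  attr(df, "feature_names") <- feature_names
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table '%s'> %d rows x %d features (+ sbp, dbp)\n",
              attr(x, "subject_id"), nrow(x), length(attr(x, "feature_names"))))
  invisible(x)
}
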