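# Tidy metric table: one row per subject x protocol x (phase) x trial x
# task x metric. Units are fixed per metric name.

.metric_table_cols <- c("subject_id", "group", "protocol", "phase",
                        "trial_index", "task", "metric_name", "value", "units")

#' Construct a metric table
#'
#' A tidy table of named biomechanical metrics. The key
#' (subject, protocol, phase, trial, task, metric) must be unique and each
#' metric name must carry a single unit string.
#'
#' @param df Data frame with columns `subject_id`, `group`
#'   ("PwP"/"Control"), `protocol`, optionally `phase`
#'   ("Baseline"/"Pre"/"Post"), `trial_index`, `task`, `metric_name`,
#'   `value`, `units`.
#' @return A `metric_table` (a data frame).
#' @export
metric_table <- function(df = NULL) {
  if (is.null(df)) {
    df <- as.data.frame(setNames(
      list(character(), character(), character(), character(), integer(),
           character(), character(), numeric(), character()),
      .metric_table_cols), stringsAsFactors = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"phase" %in% names(df)) df$phase <- NA_character_
  missing_cols <- setdiff(.metric_table_cols, names(df))
  if (length(missing_cols))
    stop("metric_table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .metric_table_cols]
  key <- do.call(paste, c(df[c("subject_id", "protocol", "phase",
                               "trial_index", "task", "metric_name")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (subject, protocol, phase, trial, task, metric) rows")
  units_per_metric <- tapply(df$units, df$metric_name, function(u) length(unique(u)))
  if (length(units_per_metric) && any(units_per_metric > 1))
    stop("units must be fixed per metric_name")
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Write a metric table to CSV
#'
#' The CSV round-trips losslessly through [read_metric_table()]. When no row
#' carries a phase, the phase column is omitted.
#'
#' @param table A [metric_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  table <- metric_table(table)          # re-validates; duplicates are fatal
  df <- as.data.frame(table)
  if (all(is.na(df$phase))) df$phase <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a metric table from CSV
#'
#' @param path CSV written by [write_metric_table()] (or matching its layout).
#' @return A [metric_table()].
#' @export
read_metric_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  if (!"phase" %in% names(df)) df$phase <- NA_character_
  df$trial_index <- as.integer(df$trial_index)
  metric_table(df)
}

# Internal: convenience builder for one metric row batch.
metric_rows <- function(subject_id, group, protocol, trial_index, task,
                        values, units, phase = NA_character_) {
  if (length(values) == 0) return(NULL)
  data.frame(subject_id = subject_id, group = group, protocol = protocol,
             phase = phase, trial_index = as.integer(trial_index), task = task,
             metric_name = names(values), value = as.numeric(values),
             units = units, stringsAsFactors = FALSE, row.names = NULL)
}
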