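# Reading, validating and writing step-level footfall tables, and pooling
# trial pairs into analyzable walks.
#
# Table dialect: comma-separated, header row, UTF-8. Times are seconds as
# decimals, heel coordinates are centimetres with y the nominal progression
# direction of the walkway.

.footfall_columns <- c("subject_id", "condition", "trial_index", "foot",
                       "contact_time", "lift_time", "heel_x", "heel_y")

#' Read a step-level footfall event table
#'
#' Reads a delimited-text table with one row per foot contact and validates
#' it: required columns present, `condition` one of [gait_conditions()],
#' `foot` either `"left"` or `"right"`, `lift_time > contact_time` on every
#' row, and same-foot events strictly ordered by contact time within each
#' subject × condition × trial. Row order within a trial is preserved.
#'
#' @param path Path to a CSV file with columns `subject_id`, `condition`,
#'   `trial_index`, `foot`, `contact_time`, `lift_time`, `heel_x`, `heel_y`.
#' @param sep Field separator (default comma).
#' @return A data.frame of validated footfall events (class
#'   `footfall_table`).
#' @seealso [pool_trials()], [simulate_full_study()]
#' @export
read_footfalls <- function(path, sep = ",") {
  if (!file.exists(path)) stop_gait("footfall file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_footfalls(df)
}

#' Validate an in-memory footfall event table
#'
#' @param df A data.frame with the footfall columns (see [read_footfalls()]).
#' @return The validated data.frame, classed `footfall_table`.
#' @export
validate_footfalls <- function(df) {
  missing <- setdiff(.footfall_columns, names(df))
  if (length(missing) > 0)
    stop_gait("footfall table is missing required column(s): %s",
              paste(missing, collapse = ", "), class = "gaitmcid_schema_error")
  df$trial_index <- as.integer(df$trial_index)
  df$foot <- tolower(as.character(df$foot))
  for (col in c("contact_time", "lift_time", "heel_x", "heel_y"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- which(!df$foot %in% c("left", "right"))
  if (length(bad) > 0)
    stop_gait("invalid foot label at row %d: %s", bad[1], df$foot[bad[1]])
  bad <- which(!df$condition %in% gait_conditions())
  if (length(bad) > 0)
    stop_gait("invalid condition at row %d: %s", bad[1], df$condition[bad[1]])
  bad <- which(!(df$lift_time > df$contact_time))
  if (length(bad) > 0)
    stop_gait("lift_time <= contact_time at row %d", bad[1])
  if (any(df$trial_index < 1L, na.rm = TRUE))
    stop_gait("trial_index must be >= 1")
  # same-foot events strictly ordered by contact_time within a trial
  key <- interaction(df$subject_id, df$condition, df$trial_index, df$foot,
                     drop = TRUE)
  for (k in levels(key)) {
    ct <- df$contact_time[key == k]
    if (length(ct) > 1 && any(diff(ct) <= 0))
      stop_gait("events of the same foot not strictly ordered by contact_time in block %s", k)
  }
  class(df) <- c("footfall_table", "data.frame")
  df
}

#' Pool a pair of walkway trials into one analyzable walk
#'
#' Step data from two walkway trials are pooled to ensure enough gait cycles
#' for variability and asymmetry estimation. Events of each trial keep their
#' internal order, and downstream stride segmentation never forms strides
#' across the trial boundary.
#'
#' @param events A footfall table (from [read_footfalls()] or
#'   [validate_footfalls()]) restricted to, or containing, one subject and
#'   condition.
#' @param trial_pair Integer vector of length 2: the two trial indices to
#'   pool (e.g. `c(1, 2)`).
#' @param subject_id,condition Optional; required if `events` spans several
#'   subjects or conditions.
#' @return A `walk` object: list with `subject_id`, `condition`,
#'   `trial_pair`, and `events` (the pooled footfall rows, trial-ordered).
#' @examples
#' ff <- synthesize_step_stream(
#'   c(slen = 112, stime = 1.16, swing = 36.4, swidth = 11.5),
#'   n_cycles = 20, seed = 1)
#' w <- pool_trials(ff, c(1, 2))
#' nrow(w$events)
#' @export
pool_trials <- function(events, trial_pair, subject_id = NULL,
                        condition = NULL) {
  if (length(trial_pair) != 2L || trial_pair[1] == trial_pair[2])
    stop_gait("trial_pair must be two distinct trial indices")
  df <- as.data.frame(events)
  if (!is.null(subject_id)) df <- df[df$subject_id == subject_id, ]
  if (!is.null(condition)) df <- df[df$condition == condition, ]
  if (nrow(df) == 0) stop_gait("no events for requested subject/condition")
  if (length(unique(df$subject_id)) != 1L)
    stop_gait("events span multiple subjects; pass subject_id")
  if (length(unique(df$condition)) != 1L)
    stop_gait("events span multiple conditions; pass condition")
  parts <- lapply(trial_pair, function(tr) {
    e <- df[df$trial_index == tr, , drop = FALSE]
    if (nrow(e) == 0)
      stop_gait("trial %d missing for subject %s, condition %s",
                tr, df$subject_id[1], df$condition[1])
    e
  })
  out <- list(subject_id = df$subject_id[1], condition = df$condition[1],
              trial_pair = as.integer(trial_pair),
              events = do.call(rbind, parts))
  rownames(out$events) <- NULL
  class(out) <- "walk"
  out
}

#' @export
print.walk <- function(x, ...) {
  cat(sprintf("<walk> subject %s, condition %s, trials (%d,%d), %d footfall events\n",
              x$subject_id, x$condition, x$trial_pair[1], x$trial_pair[2],
              nrow(x$events)))
  invisible(x)
}

#' Write and read long-format gait-metric tables
#'
#' `write_metrics()` writes a collection of per-walk metric sets as a
#' long-format CSV with one row per subject × condition × walk × metric;
#' `read_metrics()` reads it back. The round trip is lossless at 10
#' significant digits.
#'
#' @param metrics Either a long data.frame with columns `subject_id`,
#'   `condition`, `walk`, `metric`, `value`, or a list of per-walk metric
#'   sets as returned by [compute_metrics()] (each carrying `subject_id`,
#'   `condition` and `walk` attributes).
#' @param path Output CSV path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns the long data.frame.
#' @export
write_metrics <- function(metrics, path) {
  df <- as_metric_table(metrics)
  df$value <- ifelse(is.na(df$value), NA, signif(df$value, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_gait("metric file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "walk", "metric", "value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_gait("metric table is missing column(s): %s",
              paste(missing, collapse = ", "), class = "gaitmcid_schema_error")
  df
}

# normalize metric input into the long table format
as_metric_table <- function(metrics) {
  need <- c("subject_id", "condition", "walk", "metric", "value")
  if (is.data.frame(metrics)) {
    if (!all(need %in% names(metrics)))
      stop_gait("long metric table needs columns: %s",
                paste(need, collapse = ", "))
    return(metrics[, need, drop = FALSE])
  }
  if (length(metrics) == 0)
    return(stats::setNames(
      data.frame(character(), character(), integer(), character(), double(),
                 stringsAsFactors = FALSE), need))
  rows <- lapply(metrics, function(gm) {
    data.frame(subject_id = attr(gm, "subject_id") %||% NA_character_,
               condition = attr(gm, "condition") %||% NA_character_,
               walk = attr(gm, "walk") %||% NA_integer_,
               metric = names(gm), value = as.numeric(gm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a clinical-anchor table
#'
#' One row per subject with anchor scores: Functional Gait Assessment
#' (`fga`, 0–30), Falls Efficacy Scale–International (`fes_i`, 16–64), SF-12
#' physical and mental component scores (`pcs12`, `mcs12`). `mcs12` is
#' carried but unused by the MCID analysis.
#'
#' @param path CSV path with columns `subject_id`, `fga`, `fes_i`, `pcs12`,
#'   and optionally `mcs12`.
#' @return Validated data.frame.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop_gait("anchor file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_anchors(df)
}

#' @rdname read_anchors
#' @param df An in-memory anchor data.frame.
#' @export
validate_anchors <- function(df) {
  need <- c("subject_id", "fga", "fes_i", "pcs12")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_gait("anchor table is missing column(s): %s",
              paste(missing, collapse = ", "), class = "gaitmcid_schema_error")
  if (any(df$fga < 0 | df$fga > 30, na.rm = TRUE))
    stop_gait("fga out of range [0, 30]")
  if (any(df$fes_i < 16 | df$fes_i > 64, na.rm = TRUE))
    stop_gait("fes_i out of range [16, 64]")
  if (anyDuplicated(df$subject_id))
    stop_gait("duplicate subject_id in anchor table")
  df
}
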