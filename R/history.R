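# Longitudinal tracking of rotational-alignment measurements.
# The history is a flat CSV: greppable, diffable, no database.

history_columns <- c("date", "machine_id", "max_error_mm", "xgt_mm", "yab_mm",
                     "session_id", "notes")

empty_history <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(history_columns)),
                               history_columns), stringsAsFactors = FALSE)
  df$max_error_mm <- numeric(0); df$xgt_mm <- numeric(0); df$yab_mm <- numeric(0)
  df
}

#' Read a measurement history file
#'
#' @param history_file CSV path; a missing file yields an empty history.
#' @return Data frame with columns date, machine_id, max_error_mm, xgt_mm,
#'   yab_mm, session_id, notes.
#' @export
read_history <- function(history_file) {
  if (!file.exists(history_file)) return(empty_history())
  df <- utils::read.csv(history_file, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), history_columns))
    stop("history schema mismatch in ", history_file, ": expected columns ",
         paste(history_columns, collapse = ", "), call. = FALSE)
  for (col in c("max_error_mm", "xgt_mm", "yab_mm")) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !(is.na(raw) | raw %in% c("", "NA"))
    # the adjustment columns are optional; the error itself is not
    if (any(bad) || (col == "max_error_mm" && anyNA(v) && nrow(df) > 0))
      stop("malformed numeric value in history column ", col, call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Record a measurement in the history file
#'
#' Appends one row; appending an identical (date, session_id) key again is a
#' no-op, so re-running an analysis never duplicates history.
#'
#' @param history_file CSV path (created if missing).
#' @param date ISO-8601 date of the measurement.
#' @param machine_id Machine identifier.
#' @param max_rotational_error_mm Non-negative maximum rotational error.
#' @param adjustment An [adjustment_vector()] (or NULL for none).
#' @param session_id Session identifier.
#' @param notes Free text.
#' @return The updated history data frame, invisibly.
#' @export
append_record <- function(history_file, date, machine_id,
                          max_rotational_error_mm,
                          adjustment = NULL, session_id = "", notes = "") {
  if (!is.finite(max_rotational_error_mm) || max_rotational_error_mm < 0)
    stop("max_rotational_error_mm must be a non-negative number", call. = FALSE)
  hist <- read_history(history_file)
  if (nrow(hist) > 0 &&
      any(hist$date == date & hist$session_id == session_id))
    return(invisible(hist))
  row <- data.frame(date = as.character(date),
                    machine_id = as.character(machine_id),
                    max_error_mm = max_rotational_error_mm,
                    xgt_mm = if (is.null(adjustment)) NA_real_ else adjustment$x_gt_mm,
                    yab_mm = if (is.null(adjustment)) NA_real_ else adjustment$y_ab_mm,
                    session_id = as.character(session_id),
                    notes = as.character(notes),
                    stringsAsFactors = FALSE)
  hist <- rbind(hist, row)
  utils::write.csv(hist, history_file, row.names = FALSE)
  invisible(hist)
}

select_history <- function(history, machine_id = NULL, date_range = NULL) {
  sel <- history
  if (!is.null(machine_id)) sel <- sel[sel$machine_id == machine_id, ]
  if (!is.null(date_range))
    sel <- sel[sel$date >= date_range[1] & sel$date <= date_range[2], ]
  sel
}

#' Summarize maximum rotational error over a history selection
#'
#' @param history Data frame from [read_history()] (or a CSV path).
#' @param machine_id Optional machine filter.
#' @param date_range Optional length-2 ISO-date range (inclusive).
#' @return List with `n`, `mean_mm`, `sd_mm` (sample SD, n-1 denominator; 0
#'   with `sd_defined = FALSE` for a single record), `min_mm`, `max_mm`.
#' @export
summarize_history <- function(history, machine_id = NULL, date_range = NULL) {
  if (is.character(history)) history <- read_history(history)
  sel <- select_history(history, machine_id, date_range)
  if (nrow(sel) == 0) stop("empty selection: no records in range", call. = FALSE)
  x <- sel$max_error_mm
  list(n = length(x),
       mean_mm = mean(x),
       sd_mm = if (length(x) > 1) stats::sd(x) else 0,
       sd_defined = length(x) > 1,
       min_mm = min(x), max_mm = max(x))
}

#' Compare two periods of rotational-error measurements
#'
#' Welch two-sample t-test of the maximum rotational error between two
#' selections (for example pre- vs post-adjustment).
#'
#' @param history Data frame from [read_history()] (or a CSV path).
#' @param range_a,range_b Length-2 ISO-date ranges defining the groups.
#' @param machine_id Optional machine filter applied to both groups.
#' @return List with `mean_difference_mm` (A minus B), `p_value`, `n_a`,
#'   `n_b`.
#' @export
compare_groups <- function(history, range_a, range_b, machine_id = NULL) {
  if (is.character(history)) history <- read_history(history)
  a <- select_history(history, machine_id, range_a)$max_error_mm
  b <- select_history(history, machine_id, range_b)$max_error_mm
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 records for a comparison", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(mean_difference_mm = 0, p_value = 1,
                n_a = length(a), n_b = length(b)))
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_difference_mm = mean(a) - mean(b),
       p_value = tt$p.value, n_a = length(a), n_b = length(b))
}
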