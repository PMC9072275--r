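# Core time-series containers and CSV I/O: eye traces, cover schedules and
# study tables. Canonical units everywhere: seconds, degrees, positive = up.

#' Construct an eye-position trace
#'
#' A uniformly sampled vertical eye-position time series. Position is stored
#' in degrees (positive = upward); raw tracker units are converted at
#' calibration time and never stored here.
#'
#' @param t Time stamps in seconds, strictly increasing on a uniform grid.
#' @param y Vertical eye position in degrees; must be finite wherever
#'   `mask` is `FALSE`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred from the median time
#'   step. The grid is checked for uniformity against `1/fs` to 1e-6 s.
#' @param mask Logical vector marking blink/artifact samples (`TRUE` =
#'   unusable). Default all `FALSE`.
#' @return An object of class `eye_trace`: a list with elements `t`, `y`,
#'   `fs`, `mask`.
#' @export
eye_trace <- function(t, y, fs = NULL, mask = NULL) {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) < 2L) stop("an eye_trace needs at least 2 samples", call. = FALSE)
  if (length(t) != length(y)) stop("`t` and `y` lengths differ", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L]
    stop(sprintf("time stamps must be strictly increasing (violated at row %d: t=%.6f then %.6f)",
                 bad, t[bad], t[bad + 1L]), call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs)) > 1e-6) {
    bad <- which.max(abs(dt - 1 / fs))
    stop(sprintf("non-uniform sampling grid: step %d is %.6f s, expected %.6f s",
                 bad, dt[bad], 1 / fs), call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(FALSE, length(t))
  mask <- as.logical(mask)
  if (length(mask) != length(t)) stop("`mask` length differs from `t`", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  if (any(!is.finite(y[!mask]))) stop("unmasked positions must be finite", call. = FALSE)
  structure(list(t = t, y = y, fs = fs, mask = mask), class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %d samples @ %.1f Hz, %.2f s, %d masked\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1L], sum(x$mask)))
  invisible(x)
}

#' Construct a cover-switch schedule
#'
#' Ordered cover-switch times with the eye that views *after* each switch.
#' Labels must alternate between `"left"` and `"right"`.
#'
#' @param switch_times Switch times in seconds, strictly increasing.
#' @param viewing_eye_after Character vector, `"left"` or `"right"`, one per
#'   switch; consecutive labels must alternate.
#' @param period Nominal switch period in seconds (default 2).
#' @return An object of class `cover_schedule`.
#' @export
cover_schedule <- function(switch_times, viewing_eye_after, period = 2.0) {
  switch_times <- as.numeric(switch_times)
  viewing_eye_after <- as.character(viewing_eye_after)
  if (length(switch_times) != length(viewing_eye_after)) {
    stop("`switch_times` and `viewing_eye_after` lengths differ", call. = FALSE)
  }
  if (length(switch_times) > 1L && any(diff(switch_times) <= 0)) {
    stop("switch times must be strictly increasing", call. = FALSE)
  }
  if (!all(viewing_eye_after %in% c("left", "right"))) {
    stop("viewing-eye labels must be 'left' or 'right'", call. = FALSE)
  }
  if (length(viewing_eye_after) > 1L &&
      any(viewing_eye_after[-1L] == viewing_eye_after[-length(viewing_eye_after)])) {
    stop("viewing-eye labels must alternate", call. = FALSE)
  }
  structure(list(switch_times = switch_times,
                 viewing_eye_after = viewing_eye_after,
                 period = period),
            class = "cover_schedule")
}

#' @export
print.cover_schedule <- function(x, ...) {
  cat(sprintf("<cover_schedule> %d switches, period %.2f s\n",
              length(x$switch_times), x$period))
  invisible(x)
}

#' Read an eye trace from CSV
#'
#' Expects a header `t_s,y_deg` with an optional `mask` column (0/1). The
#' sampling rate is inferred from the median time step and the grid checked
#' for uniformity.
#'
#' @param path Path to a CSV file.
#' @return An [eye_trace()].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "y_deg")
  if (!all(need %in% names(df))) {
    stop(sprintf("trace file %s must have columns t_s,y_deg", path), call. = FALSE)
  }
  mask <- if ("mask" %in% names(df)) df$mask != 0 else NULL
  y <- df$y_deg
  if (!is.null(mask)) y[mask & !is.finite(y)] <- 0  # masked samples may be blank
  eye_trace(df$t_s, y, mask = mask)
}

#' Write an eye trace to CSV
#'
#' Deterministic output at 12 significant digits (round trips to better
#' than 1e-9); masked samples get `mask=1`.
#'
#' @param trace An [eye_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eye_trace"))
  df <- data.frame(t_s = formatC(trace$t, digits = 12, format = "g"),
                   y_deg = formatC(trace$y, digits = 12, format = "g"),
                   mask = as.integer(trace$mask))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cover schedule from CSV or JSON
#'
#' CSV expects header `switch_s,viewing_eye_after`; JSON expects keys
#' `switch_s` and `viewing_eye_after` (and optionally `period`).
#'
#' @param path Path to the file; format chosen by `.json` extension.
#' @return A [cover_schedule()].
#' @export
read_schedule <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(cover_schedule(obj$switch_s, obj$viewing_eye_after,
                          period = if (!is.null(obj$period)) obj$period else 2.0))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("switch_s", "viewing_eye_after")
  if (!all(need %in% names(df))) {
    stop(sprintf("schedule file %s must have columns switch_s,viewing_eye_after", path),
         call. = FALSE)
  }
  period <- if (nrow(df) > 1L) stats::median(diff(df$switch_s)) else 2.0
  cover_schedule(df$switch_s, df$viewing_eye_after, period = period)
}

#' Write a cover schedule to CSV
#'
#' @param schedule A [cover_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cover_schedule"))
  df <- data.frame(switch_s = formatC(schedule$switch_times, digits = 9, format = "g"),
                   viewing_eye_after = schedule$viewing_eye_after)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study table of per-condition records
#'
#' Expects header `subject_id,foil_pd,apct_pd,vog_pd`: for each subject and
#' induced foil strength, the true prism value, the cover-test (APCT)
#' reading, and the automated video-oculography estimate. Foil values off
#' the clinical set \{1, 2, 4, 6, 8, 10\} are accepted with a warning.
#'
#' @param path Path to a CSV file. `vog_pd` may contain `NA` (not yet
#'   estimated).
#' @return A `data.frame` with the four columns above, order preserved.
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "foil_pd", "apct_pd", "vog_pd")
  if (!all(need %in% names(df))) {
    stop(sprintf("study table %s must have columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  df <- df[need]
  validate_study_table(df)
}

#' Validate a study table
#'
#' @param df A data.frame with columns `subject_id`, `foil_pd`, `apct_pd`,
#'   `vog_pd`.
#' @return The validated data.frame.
#' @export
validate_study_table <- function(df) {
  foil_set <- c(1, 2, 4, 6, 8, 10)
  if (any(!is.finite(df$foil_pd)) || any(df$foil_pd < 0)) {
    stop("foil_pd must be finite and >= 0", call. = FALSE)
  }
  off <- setdiff(unique(df$foil_pd), foil_set)
  if (length(off)) {
    warning(sprintf("foil_pd value(s) %s are off the standard foil set {1,2,4,6,8,10}; accepted",
                    paste(off, collapse = ", ")), call. = FALSE)
  }
  if (any(is.finite(df$apct_pd) & (df$apct_pd < 0 | df$apct_pd > 10))) {
    stop("apct_pd readings must lie in [0, 10]", call. = FALSE)
  }
  if (any(is.finite(df$vog_pd) & df$vog_pd < 0)) {
    stop("vog_pd estimates must be >= 0", call. = FALSE)
  }
  df
}

#' Write a study table to CSV
#'
#' @param df Study table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
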