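#' Velocity traces
#'
#' A velocity trace is one animal-session's uniformly sampled speed series,
#' stored as a tibble with columns `time_s` (session clock, seconds) and
#' `velocity_cm_s`, plus `animal_id`, `session_id` and `sample_period`
#' attributes. The nominal tracker output rate is 3.75 Hz (sample period
#' 1/3.75 s).
#'
#' @param velocity_cm_s Numeric vector of speeds (cm/s), finite and >= 0.
#' @param animal_id,session_id Identifiers; `session_id` is one of
#'   `"conditioning"`, `"extinction"`, `"extinction_test"`.
#' @param sample_period Sampling interval in seconds (default `1/3.75`).
#' @param start_time_s Session-clock time of the first sample (default 0).
#'
#' @return A `velocity_trace` tibble.
#' @examples
#' tr <- velocity_trace(rep(0, 225), "rat01", "conditioning")
#' nrow(tr)  # 225 samples = 60 s at 3.75 Hz
#' @export
velocity_trace <- function(velocity_cm_s, animal_id, session_id,
                           sample_period = 1 / 3.75, start_time_s = 0) {
  v <- as.numeric(velocity_cm_s)
  if (any(!is.finite(v))) abort("All velocities must be finite.")
  if (any(v < 0)) abort("negative velocity: all velocities must be >= 0.")
  out <- tibble(
    time_s = start_time_s + (seq_along(v) - 1) * sample_period,
    velocity_cm_s = v
  )
  attr(out, "animal_id") <- animal_id
  attr(out, "session_id") <- session_id
  attr(out, "sample_period") <- sample_period
  class(out) <- c("velocity_trace", class(out))
  out
}

trace_sample_period <- function(trace) {
  sp <- attr(trace, "sample_period")
  if (!is.null(sp)) return(sp)
  stats::median(diff(trace$time_s))
}

#' Load a velocity trace from delimited text
#'
#' Reads a CSV (or other delimited file) with a header naming a time column in
#' seconds and a velocity column in cm/s. The time axis must be uniformly
#' spaced within a relative tolerance of `1e-3` of the sample period. Gaps of
#' at most `max_gap` consecutive missing samples — missing rows or `NA`
#' velocities — are filled by linear interpolation; longer gaps are an error,
#' as are negative or non-finite velocities after interpolation.
#'
#' @param path Path to the delimited file.
#' @param animal_id,session_id Identifiers attached to the trace.
#' @param time_col,velocity_col Column names (defaults `time_s`,
#'   `velocity_cm_s`).
#' @param max_gap Maximum run of missing samples to interpolate (default 2).
#' @param delim Field delimiter (default `,`).
#'
#' @return A validated [velocity_trace()].
#' @export
load_trace <- function(path, animal_id, session_id,
                       time_col = "time_s", velocity_col = "velocity_cm_s",
                       max_gap = 2, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c(time_col, velocity_col) %in% names(raw))) {
    abort(sprintf(
      "malformed header: expected columns '%s' and '%s', found: %s",
      time_col, velocity_col, toString(names(raw))
    ))
  }
  tt <- as.numeric(raw[[time_col]])
  vv <- as.numeric(raw[[velocity_col]])
  if (length(tt) < 2) abort("Trace must contain at least 2 samples.")
  if (is.unsorted(tt, strictly = TRUE)) abort("Time column must be strictly increasing.")

  dt <- diff(tt)
  period <- stats::median(dt)
  # each observed step must sit on the sample grid (integer multiple of the
  # period within relative tolerance); multiples > 1 are missing rows
  steps <- dt / period
  k <- round(steps)
  if (any(k < 1) || any(abs(steps - k) > 1e-3 * pmax(1, k))) {
    abort("non-uniform spacing: time steps are not integer multiples of the sample period.")
  }
  if (any(k - 1 > max_gap)) {
    abort(sprintf("gap too long: more than %d consecutive samples missing.", max_gap))
  }

  # expand onto the full grid, leaving NA at missing rows
  idx <- c(0, cumsum(k)) + 1
  n <- idx[length(idx)]
  v <- rep(NA_real_, n)
  v[idx] <- vv

  # NA runs (from missing rows or NA velocities) interpolated if short
  na_runs <- rle(is.na(v))
  if (any(na_runs$values & na_runs$lengths > max_gap)) {
    abort(sprintf("gap too long: more than %d consecutive samples missing.", max_gap))
  }
  if (anyNA(v)) {
    if (is.na(v[1]) || is.na(v[n])) {
      abort("Trace may not start or end with missing samples.")
    }
    v <- stats::approx(seq_len(n)[!is.na(v)], v[!is.na(v)], xout = seq_len(n))$y
  }
  if (any(v < 0)) abort("negative velocity: velocities must be >= 0.")

  velocity_trace(v, animal_id, session_id,
                 sample_period = period, start_time_s = tt[1])
}

#' Write a velocity trace to CSV
#'
#' Columns `time_s,velocity_cm_s`, full precision; round-trips through
#' [load_trace()].
#'
#' @param trace A `velocity_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("time_s", "velocity_cm_s")], path)
  invisible(path)
}

#' Check a trace covers its session
#'
#' The trace must span the session from time 0 through the last trial's
#' analysis window (post-shock end on US trials).
#'
#' @param trace A `velocity_trace`.
#' @param schedule The session's `session_schedule`.
#' @return The trace, invisibly, if it covers the session.
#' @export
check_trace_covers <- function(trace, schedule) {
  needed <- session_duration(schedule, tail_s = 0)
  have <- trace$time_s[nrow(trace)] + trace_sample_period(trace)
  if (have < needed - 1e-9) {
    abort(sprintf(
      "Trace covers %.1f s but the schedule requires %.1f s.", have, needed
    ))
  }
  invisible(trace)
}
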