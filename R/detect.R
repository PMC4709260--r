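#' Detect dart events in a velocity trace
#'
#' A dart is a discrete high-velocity event: a local maximum of the sampled
#' velocity series with peak value at or above `min_peak_velocity`
#' (23.5 cm/s by default), with retained peaks separated by at least
#' `min_interpeak_interval` (0.8 s by default).
#'
#' Conventions on the sampled series: a sample is a local maximum when it is
#' strictly greater than the nearest differing values on both sides; for
#' plateaus of equal values the first sample of the plateau is the peak; the
#' first and last samples can never be peaks. Spacing is enforced by greedy
#' retention in descending peak-height order (ties broken by earlier time), a
#' candidate being dropped when it lies closer than `min_interpeak_interval`
#' to an already-retained peak. This matches the common peak-finder behavior
#' of a minimum peak distance filter.
#'
#' @param trace A [velocity_trace()].
#' @param params A [detection_params()].
#' @return A tibble of events with columns `animal_id`, `session_id`,
#'   `time_s`, `peak_velocity_cm_s`, `trial_index` (`NA` until assigned) and
#'   `epoch` (`NA` until assigned); ordered by time.
#' @examples
#' tr <- velocity_trace(c(0, 0, 10, 30, 10, 0, 0), "r1", "conditioning")
#' detect_darts(tr)
#' @export
detect_darts <- function(trace, params = detection_params()) {
  v <- trace$velocity_cm_s
  if (length(v) < 3) abort("Trace must contain at least 3 samples.")
  cand <- local_maxima(v)
  cand <- cand[v[cand] >= params$min_peak_velocity]
  keep <- enforce_min_spacing(trace$time_s[cand], v[cand],
                              params$min_interpeak_interval)
  cand <- sort(cand[keep])
  tibble(
    animal_id = attr(trace, "animal_id") %||% NA_character_,
    session_id = attr(trace, "session_id") %||% NA_character_,
    time_s = trace$time_s[cand],
    peak_velocity_cm_s = v[cand],
    trial_index = NA_integer_,
    epoch = NA_character_
  )
}

# indices of strict local maxima; plateaus collapse to their first sample;
# endpoints excluded (no two-sided neighborhood)
local_maxima <- function(v) {
  r <- rle(v)
  n_runs <- length(r$values)
  if (n_runs < 3) return(integer(0))
  run_start <- cumsum(c(1, r$lengths[-n_runs]))
  interior <- 2:(n_runs - 1)
  is_peak <- r$values[interior] > r$values[interior - 1] &
    r$values[interior] > r$values[interior + 1]
  run_start[interior][is_peak]
}

# greedy minimum-distance filter: descending height, ties by earlier time;
# returns a logical keep vector aligned with the input order
enforce_min_spacing <- function(times, heights, min_sep) {
  n <- length(times)
  if (n <= 1) return(rep(TRUE, n))
  ord <- order(-heights, times)
  keep <- logical(n)
  kept_times <- numeric(0)
  for (i in ord) {
    if (all(abs(times[i] - kept_times) >= min_sep)) {
      keep[i] <- TRUE
      kept_times <- c(kept_times, times[i])
    }
  }
  keep
}

#' Score freezing bouts from a velocity trace
#'
#' Freezing is immobility: maximal runs of consecutive samples with velocity
#' below `freezing_velocity_threshold`, kept only when they last at least
#' `min_freeze_bout` seconds (2 s by default). A run of `k` samples starting
#' at sample time `t` spans `[t, t + k * sample_period)`.
#'
#' @inheritParams detect_darts
#' @return A tibble of bouts with columns `animal_id`, `session_id`,
#'   `start_s`, `end_s`; ordered and non-overlapping.
#' @export
score_freezing <- function(trace, params = detection_params()) {
  v <- trace$velocity_cm_s
  period <- trace_sample_period(trace)
  r <- rle(v < params$freezing_velocity_threshold)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  still <- which(r$values)
  start_s <- trace$time_s[starts_idx[still]]
  end_s <- start_s + r$lengths[still] * period
  ok <- (end_s - start_s) >= params$min_freeze_bout - 1e-9
  tibble(
    animal_id = attr(trace, "animal_id") %||% NA_character_,
    session_id = attr(trace, "session_id") %||% NA_character_,
    start_s = start_s[ok],
    end_s = end_s[ok]
  )
}

#' Percent time freezing within a window
#'
#' 100 x (total overlap of bouts with the window) / (window length), bouts
#' clipped at the window edges.
#'
#' @param bouts A bout tibble from [score_freezing()].
#' @param window Length-2 numeric, the half-open window `[start, end)` in
#'   seconds.
#' @return Percentage in `[0, 100]`.
#' @examples
#' bouts <- tibble::tibble(start_s = 10, end_s = 25)
#' percent_freezing(bouts, c(0, 30))  # 50
#' @export
percent_freezing <- function(bouts, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(start, end) with end > start.")
  }
  if (nrow(bouts) == 0) return(0)
  overlap <- pmax(0, pmin(bouts$end_s, window[2]) - pmax(bouts$start_s, window[1]))
  100 * sum(overlap) / (window[2] - window[1])
}
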