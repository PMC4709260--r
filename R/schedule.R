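#' Session schedules for the three-day fear-conditioning protocol
#'
#' A session schedule is a tibble with one row per trial and the columns
#' `trial` (1-based ordinal), `cs_onset_s`, `cs_duration_s`, `has_us` and
#' `us_duration_s`, carrying the session identity and acclimation duration as
#' attributes. All times are on the session clock (0 = recording start); the
#' acclimation period occupies `[0, acclimation_s)`. The footshock (US)
#' co-terminates with the tone (CS), so `us_onset = cs_onset + cs_duration -
#' us_duration`.
#'
#' The canonical protocol: `conditioning` (day 1) is 5 habituation tones
#' followed by 7 tone-shock pairings (trials 6-12 carry the US); `extinction`
#' (day 2) is 20 tone-alone presentations; `extinction_test` (day 3) is 3
#' tone-alone presentations. Inter-trial onset gaps are drawn uniformly from
#' a 2-6 min range (4 min mean), and the first tone follows the 4-min
#' acclimation plus one such gap.
#'
#' @param session_id One of `"conditioning"`, `"extinction"`,
#'   `"extinction_test"`.
#' @param cs_onsets Optional numeric vector of CS onset times (seconds). When
#'   `NULL`, onsets are drawn using `seed`.
#' @param seed Integer seed for the inter-trial interval draws (required when
#'   `cs_onsets` is `NULL`).
#' @param acclimation_s Acclimation duration in seconds (default 240).
#' @param iti_range_s Length-2 numeric, allowed range of consecutive CS onset
#'   gaps in seconds (default `c(120, 360)`, i.e. 2-6 min).
#' @param cs_duration_s Tone duration in seconds (default 30).
#' @param us_duration_s Shock duration in seconds (default 0.5).
#'
#' @return A `session_schedule` tibble (one row per trial).
#' @examples
#' sched <- build_schedule("conditioning", seed = 1)
#' sum(sched$has_us)  # 7 tone-shock pairings
#' @export
build_schedule <- function(session_id,
                           cs_onsets = NULL,
                           seed = NULL,
                           acclimation_s = 240,
                           iti_range_s = c(120, 360),
                           cs_duration_s = 30,
                           us_duration_s = 0.5) {
  spec <- session_spec(session_id)
  n_trials <- spec$n_trials

  if (is.null(cs_onsets)) {
    if (is.null(seed)) {
      abort("`seed` is required when `cs_onsets` is not supplied.")
    }
    cs_onsets <- withr_seed(seed, {
      gaps <- runif(n_trials, iti_range_s[1], iti_range_s[2])
      acclimation_s + cumsum(gaps)
    })
  }
  if (length(cs_onsets) != n_trials) {
    abort(sprintf(
      "Session '%s' requires %d CS onsets, got %d.",
      session_id, n_trials, length(cs_onsets)
    ))
  }

  sched <- tibble(
    trial = seq_len(n_trials),
    cs_onset_s = as.numeric(cs_onsets),
    cs_duration_s = cs_duration_s,
    has_us = seq_len(n_trials) > spec$n_no_us,
    us_duration_s = ifelse(seq_len(n_trials) > spec$n_no_us, us_duration_s, 0)
  )
  sched <- new_session_schedule(sched, session_id, acclimation_s, iti_range_s)
  validate_schedule(sched)
  sched
}

#' Construct a schedule from explicit trial specifications
#'
#' Low-level constructor for non-canonical sessions (custom trial counts or
#' timings). The canonical three-day protocol sessions should come from
#' [build_schedule()], which also enforces the conditioning US pattern.
#'
#' @param trials Data frame with columns `trial`, `cs_onset_s`,
#'   `cs_duration_s`, `has_us`, `us_duration_s`.
#' @param session_id Session label.
#' @inheritParams build_schedule
#' @return A validated `session_schedule`.
#' @export
session_schedule <- function(trials, session_id = "custom",
                             acclimation_s = 240,
                             iti_range_s = c(120, 360)) {
  sched <- new_session_schedule(trials, session_id, acclimation_s, iti_range_s)
  validate_schedule(sched)
  sched
}

session_spec <- function(session_id) {
  switch(session_id,
    conditioning = list(n_trials = 12L, n_no_us = 5L),
    extinction = list(n_trials = 20L, n_no_us = 20L),
    extinction_test = list(n_trials = 3L, n_no_us = 3L),
    abort(sprintf(
      "Unknown session_id '%s' (expected conditioning, extinction or extinction_test).",
      session_id
    ))
  )
}

new_session_schedule <- function(trials, session_id, acclimation_s, iti_range_s) {
  out <- as_tibble(trials)
  attr(out, "session_id") <- session_id
  attr(out, "acclimation_s") <- acclimation_s
  attr(out, "iti_range_s") <- iti_range_s
  class(out) <- c("session_schedule", class(out))
  out
}

#' Validate a session schedule
#'
#' Checks trial ordering, positive durations, US/CS containment, overlap of
#' successive trial windows (through the 30-s post-shock window on US trials)
#' and that onset gaps fall within the configured inter-trial range.
#'
#' @param schedule A `session_schedule`.
#' @return The schedule, invisibly, if valid; otherwise an error.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule))
  needed <- c("trial", "cs_onset_s", "cs_duration_s", "has_us", "us_duration_s")
  missing_cols <- setdiff(needed, names(schedule))
  if (length(missing_cols) > 0) {
    abort(paste0("Schedule is missing columns: ", toString(missing_cols)))
  }
  if (any(schedule$cs_duration_s <= 0)) abort("cs_duration_s must be > 0.")
  if (any(schedule$has_us & schedule$us_duration_s >= schedule$cs_duration_s)) {
    abort("us_duration_s must be < cs_duration_s on US trials.")
  }
  if (is.unsorted(schedule$cs_onset_s, strictly = TRUE)) {
    abort("Trials must be strictly ordered by cs_onset_s.")
  }
  sid <- attr(schedule, "session_id")
  if (identical(sid, "conditioning")) {
    if (!identical(which(schedule$has_us), 6:12)) {
      abort("Conditioning sessions must have trials 1-5 without US and 6-12 with US.")
    }
  }
  # trial windows extend to post-shock end on US trials
  ends <- schedule$cs_onset_s + schedule$cs_duration_s +
    ifelse(schedule$has_us, 35, 0)
  n <- nrow(schedule)
  if (n > 1 && any(ends[-n] > schedule$cs_onset_s[-1])) {
    abort("Trial windows overlap (including post-shock windows).")
  }
  iti_range <- attr(schedule, "iti_range_s") %||% c(120, 360)
  gaps <- diff(schedule$cs_onset_s)
  if (length(gaps) > 0 &&
      any(gaps < iti_range[1] - 1e-9 | gaps > iti_range[2] + 1e-9)) {
    abort("Inter-trial onset gaps fall outside the configured range.")
  }
  invisible(schedule)
}

#' Session duration implied by a schedule
#'
#' End of the last trial's analysis window (post-shock end on US trials, CS
#' offset otherwise) plus a trailing buffer.
#'
#' @param schedule A `session_schedule`.
#' @param tail_s Trailing buffer in seconds (default 30).
#' @return Duration in seconds.
#' @export
session_duration <- function(schedule, tail_s = 30) {
  last <- nrow(schedule)
  end <- schedule$cs_onset_s[last] + schedule$cs_duration_s[last] +
    if (schedule$has_us[last]) 35 else 0
  end + tail_s
}

#' Read and write schedules as JSON
#'
#' The on-disk format is a JSON object with keys `session_id`,
#' `acclimation_s` and `trials`, the latter an array of objects with keys
#' `index`, `cs_onset_s`, `cs_duration_s`, `has_us`, `us_duration_s`.
#'
#' @param schedule A `session_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   the `session_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  obj <- list(
    session_id = attr(schedule, "session_id"),
    acclimation_s = attr(schedule, "acclimation_s"),
    iti_range_s = attr(schedule, "iti_range_s"),
    trials = purrr::pmap(schedule, function(trial, cs_onset_s, cs_duration_s,
                                            has_us, us_duration_s) {
      list(
        index = trial, cs_onset_s = cs_onset_s, cs_duration_s = cs_duration_s,
        has_us = has_us, us_duration_s = us_duration_s
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trials <- purrr::map_dfr(obj$trials, function(tr) {
    tibble(
      trial = as.integer(tr$index),
      cs_onset_s = as.numeric(tr$cs_onset_s),
      cs_duration_s = as.numeric(tr$cs_duration_s),
      has_us = isTRUE(tr$has_us),
      us_duration_s = as.numeric(tr$us_duration_s)
    )
  })
  sched <- new_session_schedule(
    trials, obj$session_id, as.numeric(obj$acclimation_s),
    as.numeric(unlist(obj$iti_range_s %||% list(120, 360)))
  )
  validate_schedule(sched)
  sched
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
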