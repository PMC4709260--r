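#' Build the four analysis epochs for a session
#'
#' The analysis epochs are: a single session-level 60-s pre-CS window ending
#' at the first CS onset; per trial, the 30-s CS window; and, on US trials
#' only, a 5-s shock-response window starting at US onset and the following
#' 30-s post-shock window. All windows are half-open `[start, end)`.
#'
#' The shock-response window is anchored at US onset (CS offset minus the
#' 0.5-s shock), so it overlaps the final 0.5 s of the CS; event assignment
#' gives shock-response precedence there, keeping the four analysis epochs
#' effectively disjoint.
#'
#' @param schedule A `session_schedule`.
#' @param pre_cs_s Pre-CS window length, seconds (default 60).
#' @param shock_window_s Shock-response window length, seconds (default 5).
#' @param post_shock_window_s Post-shock window length, seconds (default 30).
#' @return An `epoch_windows` tibble with columns `epoch`, `trial`,
#'   `start_s`, `end_s`; the schedule travels along as an attribute.
#' @examples
#' sched <- build_schedule("conditioning", seed = 1)
#' build_epochs(sched)
#' @export
build_epochs <- function(schedule, pre_cs_s = 60, shock_window_s = 5,
                         post_shock_window_s = 30) {
  validate_schedule(schedule)
  first_cs <- schedule$cs_onset_s[1]
  if (first_cs < pre_cs_s) {
    abort("First CS onset precedes the pre-CS window: session too short.")
  }
  pre <- tibble(
    epoch = "pre_cs", trial = NA_integer_,
    start_s = first_cs - pre_cs_s, end_s = first_cs
  )
  cs <- tibble(
    epoch = "cs", trial = schedule$trial,
    start_s = schedule$cs_onset_s,
    end_s = schedule$cs_onset_s + schedule$cs_duration_s
  )
  us_trials <- dplyr::filter(schedule, .data$has_us)
  shock <- post <- tibble(
    epoch = character(), trial = integer(),
    start_s = numeric(), end_s = numeric()
  )
  if (nrow(us_trials) > 0) {
    us_onset <- us_trials$cs_onset_s + us_trials$cs_duration_s - us_trials$us_duration_s
    shock <- tibble(
      epoch = "shock_response", trial = us_trials$trial,
      start_s = us_onset, end_s = us_onset + shock_window_s
    )
    post <- tibble(
      epoch = "post_shock", trial = us_trials$trial,
      start_s = us_onset + shock_window_s,
      end_s = us_onset + shock_window_s + post_shock_window_s
    )
  }
  out <- dplyr::bind_rows(pre, cs, shock, post)
  attr(out, "schedule") <- schedule
  class(out) <- c("epoch_windows", class(out))
  out
}

epoch_schedule <- function(epochs) {
  sched <- attr(epochs, "schedule")
  if (is.null(sched)) abort("Epoch windows are missing their schedule attribute.")
  sched
}

#' Assign dart events to trial epochs
#'
#' Labels each event with the epoch containing its time. Precedence where
#' windows overlap: `shock_response` beats `cs` (the 0.5-s shock tail of the
#' tone), trial windows beat the session-level `pre_cs`, and times in no
#' window are `acclimation` (before the acclimation end) or `iti`.
#' `trial_index` is set for trial-scoped labels and `NA` otherwise.
#'
#' @param events Event tibble from [detect_darts()].
#' @param epochs An `epoch_windows` from [build_epochs()].
#' @return The event tibble with `epoch` and `trial_index` filled in.
#' @export
assign_events <- function(events, epochs) {
  sched <- epoch_schedule(epochs)
  acclimation_s <- attr(sched, "acclimation_s")
  session_end <- session_duration(sched)
  precedence <- c(shock_response = 1, cs = 2, post_shock = 3, pre_cs = 4)

  lab <- purrr::map(events$time_s, function(t) {
    if (t > session_end) {
      abort(sprintf("Event at %.2f s lies beyond the session extent (%.2f s).",
                    t, session_end))
    }
    hit <- epochs[epochs$start_s <= t & t < epochs$end_s, ]
    if (nrow(hit) > 0) {
      hit <- hit[order(precedence[hit$epoch]), ]
      list(epoch = hit$epoch[1], trial = hit$trial[1])
    } else if (t < acclimation_s) {
      list(epoch = "acclimation", trial = NA_integer_)
    } else {
      list(epoch = "iti", trial = NA_integer_)
    }
  })
  events$epoch <- purrr::map_chr(lab, "epoch")
  events$trial_index <- purrr::map_int(lab, ~ as.integer(.x$trial))
  events
}

#' Per-trial and per-session behavioral metrics for one animal-session
#'
#' Computes the headline metrics: per trial, the CS dart rate (darts/min over
#' the 30-s tone), CS percent freezing, and on US trials the shock-response
#' dart count, maximum and mean shock-response velocity, and post-shock dart
#' rate; per session, the pre-CS dart rate, the total dart count (all
#' detected events, whatever their epoch) and the mean shock-response
#' velocity (across-trials mean of the within-window mean velocity by
#' default; `shock_summary = "max"` averages the per-trial maxima instead).
#'
#' @param events Labeled events from [assign_events()].
#' @param bouts Freezing bouts from [score_freezing()].
#' @param trace The animal-session's [velocity_trace()].
#' @param epochs The session's [build_epochs()] windows.
#' @param shock_summary `"mean"` (default) or `"max"`: per-trial summary
#'   entering the session-level mean shock-response velocity.
#' @return An `animal_metrics` object; [tidy()] returns the per-trial tibble,
#'   [glance()] the one-row session summary.
#' @export
compute_metrics <- function(events, bouts, trace, epochs,
                            shock_summary = c("mean", "max")) {
  shock_summary <- match.arg(shock_summary)
  sched <- epoch_schedule(epochs)
  ids <- unique(stats::na.omit(c(events$animal_id, attr(trace, "animal_id"))))
  if (length(ids) > 1) abort("Inputs mix more than one animal id.")
  sids <- unique(stats::na.omit(c(events$session_id, attr(trace, "session_id"))))
  if (length(sids) > 1) abort("Inputs mix more than one session id.")
  animal_id <- if (length(ids)) ids else NA_character_
  session_id <- if (length(sids)) sids else NA_character_

  win_events <- function(w) {
    if (w$epoch[1] %in% c("cs", "shock_response", "post_shock")) {
      sum(events$epoch == w$epoch & !is.na(events$trial_index) &
            events$trial_index == w$trial)
    } else {
      sum(events$epoch == w$epoch)
    }
  }
  win_rate <- function(w) win_events(w) / ((w$end_s - w$start_s) / 60)

  trial_rows <- purrr::map_dfr(sched$trial, function(tr) {
    cs_w <- epochs[epochs$epoch == "cs" & !is.na(epochs$trial) & epochs$trial == tr, ]
    row <- tibble(
      animal_id = animal_id, session_id = session_id, trial = tr,
      cs_dart_rate = win_rate(cs_w),
      cs_freezing = percent_freezing(bouts, c(cs_w$start_s, cs_w$end_s)),
      shock_dart_count = NA_real_, shock_max_velocity = NA_real_,
      shock_mean_velocity = NA_real_, post_shock_dart_rate = NA_real_
    )
    sh_w <- epochs[epochs$epoch == "shock_response" & !is.na(epochs$trial) &
                     epochs$trial == tr, ]
    if (nrow(sh_w) == 1) {
      in_w <- trace$time_s >= sh_w$start_s & trace$time_s < sh_w$end_s
      row$shock_dart_count <- win_events(sh_w)
      row$shock_max_velocity <- max(trace$velocity_cm_s[in_w])
      row$shock_mean_velocity <- mean(trace$velocity_cm_s[in_w])
      ps_w <- epochs[epochs$epoch == "post_shock" & !is.na(epochs$trial) &
                       epochs$trial == tr, ]
      row$post_shock_dart_rate <- win_rate(ps_w)
    }
    row
  })

  pre_w <- epochs[epochs$epoch == "pre_cs", ]
  shock_per_trial <- switch(shock_summary,
    mean = trial_rows$shock_mean_velocity,
    max = trial_rows$shock_max_velocity
  )
  session_row <- tibble(
    animal_id = animal_id, session_id = session_id,
    pre_cs_dart_rate = win_rate(pre_w),
    total_dart_count = nrow(events),
    mean_shock_response_velocity = if (all(is.na(shock_per_trial))) {
      NA_real_
    } else {
      mean(shock_per_trial, na.rm = TRUE)
    }
  )
  structure(
    list(trial = trial_rows, session = session_row),
    class = "animal_metrics"
  )
}

#' @method tidy animal_metrics
#' @export
tidy.animal_metrics <- function(x, ...) x$trial

#' @method glance animal_metrics
#' @export
glance.animal_metrics <- function(x, ...) x$session

#' @export
print.animal_metrics <- function(x, ...) {
  cat("<animal_metrics> ", x$session$animal_id, " / ", x$session$session_id,
      "\n", sep = "")
  print(x$session)
  print(x$trial)
  invisible(x)
}

#' Peri-CS dart-rate histogram
#'
#' Re-times each event relative to its trial's CS onset and counts events in
#' half-open bins (4 s wide by default) across a span around the onset,
#' converting counts to darts/min. Bin edges are anchored at CS onset (a bin
#' always starts at 0 s) and the span is widened outward to whole bins, so
#' the default -30 to +70 s view yields 26 bins from -32 to +72 s. One row
#' per trial, one column per bin.
#' Events are binned by time alone (epoch labels are not consulted), so the
#' histogram shows the full temporal organization of darting around the tone.
#'
#' @param events Event tibble (labels not required).
#' @param schedule The session's `session_schedule`.
#' @param bin_width Bin width in seconds (default 4).
#' @param span Length-2 numeric, span around CS onset in seconds (default
#'   `c(-30, 70)`).
#' @return A `peri_cs_histogram`: a trials x bins matrix of darts/min with
#'   bin left edges as column names; [autoplot()] draws it as a heatmap.
#' @export
peri_cs_histogram <- function(events, schedule, bin_width = 4,
                              span = c(-30, 70)) {
  if (bin_width <= 0) abort("bin_width must be > 0.")
  validate_schedule(schedule)
  edges <- seq(-ceiling(-span[1] / bin_width) * bin_width,
               ceiling(span[2] / bin_width) * bin_width, by = bin_width)
  n_bins <- length(edges) - 1
  mat <- matrix(0, nrow = nrow(schedule), ncol = n_bins,
                dimnames = list(trial = schedule$trial, bin = edges[-length(edges)]))
  for (i in seq_len(nrow(schedule))) {
    rel <- events$time_s - schedule$cs_onset_s[i]
    rel <- rel[rel >= edges[1] & rel < edges[length(edges)]]
    if (length(rel) > 0) {
      counts <- tabulate(findInterval(rel, edges), nbins = n_bins)
      mat[i, ] <- counts / (bin_width / 60)
    }
  }
  structure(mat, class = c("peri_cs_histogram", "matrix"),
            bin_width = bin_width, span = span)
}

#' Element-wise mean of peri-CS histograms across animals
#'
#' @param histograms List of conformable [peri_cs_histogram()] matrices.
#' @return A `peri_cs_histogram` of the element-wise means.
#' @export
average_histograms <- function(histograms) {
  if (length(histograms) == 0) abort("Need at least one histogram.")
  dims <- unique(purrr::map(histograms, dim))
  if (length(dims) != 1) abort("Histograms must have identical dimensions.")
  out <- Reduce(`+`, histograms) / length(histograms)
  attributes(out) <- attributes(histograms[[1]])
  out
}
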