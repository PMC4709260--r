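#' Simulate one animal-session velocity trace with planted ground truth
#'
#' Builds a velocity trace in three layers: (1) a two-state freeze/move
#' semi-Markov background with exponential dwell times — near-zero jitter
#' (clamped below the freezing threshold) while frozen, log-normal speeds
#' while moving; (2) dart events from an inhomogeneous Poisson process whose
#' rate is the phenotype's baseline except during CS windows (per-trial CS
#' rates) and post-shock windows, thinned so planted events keep at least the
#' minimum interpeak separation plus one sample period before being snapped
#' to the sample grid; each dart is rendered as a smooth Gaussian-shaped
#' pulse whose peak velocity is drawn around the phenotype's pulse mean
#' (floored above the detection threshold); (3) on every US trial, one
#' guaranteed shock burst placed inside the shock-response window. Pulses
#' combine with the background by pointwise maximum, so every planted event
#' is a strict local maximum at or above the dart threshold.
#'
#' The ground-truth log records every planted pulse (darts and shock bursts),
#' the background freeze intervals, the phenotype label and the planted
#' Darter status, so detector and classifier performance can be scored
#' exactly.
#'
#' @param params A [phenotype_params()].
#' @param schedule A `session_schedule`.
#' @param seed Integer seed (required; the simulation is fully reproducible).
#' @param sample_period Sampling interval in seconds (default `1/3.75`).
#' @param min_separation Minimum separation between planted events, seconds
#'   (default 0.8, the detector's interpeak interval).
#' @return A list with elements `trace` (a [velocity_trace()]) and `truth`
#'   (a `ground_truth` list: `events` tibble with `time_s`,
#'   `peak_velocity_cm_s`, `kind`; `freeze_bouts` tibble; `label`; `darter`).
#' @export
simulate_animal <- function(params, schedule, seed,
                            sample_period = 1 / 3.75,
                            min_separation = 0.8) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  stopifnot(inherits(params, "phenotype_params"))
  validate_schedule(schedule)
  withr_seed(seed, simulate_animal_impl(params, schedule, sample_period,
                                        min_separation))
}

simulate_animal_impl <- function(params, schedule, sample_period, min_sep) {
  total_s <- session_duration(schedule, tail_s = 30)
  n <- floor(total_s / sample_period) + 1
  times <- (seq_len(n) - 1) * sample_period

  ## --- background: alternate freeze/move exponential dwells ---
  p_move <- params$move_bout_mean /
    (params$move_bout_mean + params$freeze_bout_mean)
  state <- if (runif(1) < p_move) "move" else "freeze"
  bounds <- 0
  states <- character(0)
  while (bounds[length(bounds)] < total_s) {
    mean_dwell <- if (state == "move") params$move_bout_mean else params$freeze_bout_mean
    bounds <- c(bounds, bounds[length(bounds)] + rexp(1, 1 / mean_dwell))
    states <- c(states, state)
    state <- if (state == "move") "freeze" else "move"
  }
  seg <- findInterval(times, bounds, rightmost.closed = FALSE)
  seg[seg > length(states)] <- length(states)
  moving <- states[seg] == "move"

  cv <- params$baseline_speed_sd / params$baseline_speed_mean
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(params$baseline_speed_mean) - sdlog^2 / 2
  v <- numeric(n)
  v[moving] <- stats::rlnorm(sum(moving), meanlog, sdlog)
  v[!moving] <- pmin(abs(rnorm(sum(!moving), 0, 0.3)), 1.9)

  ## --- planted events ---
  us_trials <- schedule[schedule$has_us, ]
  us_onset <- us_trials$cs_onset_s + us_trials$cs_duration_s - us_trials$us_duration_s
  shock_win <- cbind(us_onset, us_onset + 5)

  cs_rates <- cs_rates_for(params, nrow(schedule),
                           attr(schedule, "session_id"))
  rate_windows <- dplyr::bind_rows(
    tibble(start = schedule$cs_onset_s,
           end = schedule$cs_onset_s + schedule$cs_duration_s,
           rate = cs_rates),
    if (nrow(us_trials) > 0) {
      tibble(start = us_onset + 5, end = us_onset + 35,
             rate = params$post_shock_dart_rate)
    }
  )
  # shock-response windows carry no random darts (a guaranteed burst instead)
  blocked <- if (nrow(us_trials) > 0) {
    tibble(start = shock_win[, 1], end = shock_win[, 2], rate = 0)
  }
  margin <- 2 * sample_period
  segments <- flatten_rate_segments(
    dplyr::bind_rows(rate_windows, blocked),
    lo = margin, hi = total_s - margin,
    base_rate = params$baseline_dart_rate
  )
  dart_times <- unlist(purrr::pmap(segments, function(start, end, rate) {
    k <- rpois(1, rate * (end - start) / 60)
    if (k == 0) numeric(0) else runif(k, start, end)
  }))

  burst_times <- numeric(0)
  burst_peaks <- numeric(0)
  if (params$shock_burst_peak_mean > 0 && nrow(us_trials) > 0) {
    burst_times <- runif(nrow(us_trials),
                         shock_win[, 1] + 0.5, shock_win[, 2] - 0.5)
    burst_peaks <- pmax(25, rnorm(nrow(us_trials),
                                  params$shock_burst_peak_mean,
                                  params$shock_burst_peak_sd))
  }

  # hard-core thinning at min separation + one period (snap-safe); shock
  # bursts are guaranteed, darts yield to them and to earlier darts
  sep <- min_sep + sample_period
  kept <- burst_times
  dart_times <- sort(dart_times)
  keep_dart <- logical(length(dart_times))
  for (i in seq_along(dart_times)) {
    if (length(kept) == 0 || all(abs(dart_times[i] - kept) >= sep)) {
      keep_dart[i] <- TRUE
      kept <- c(kept, dart_times[i])
    }
  }
  dart_times <- dart_times[keep_dart]
  dart_peaks <- pmax(25, rnorm(length(dart_times),
                               params$dart_pulse_peak_mean,
                               params$dart_pulse_peak_sd))

  ev <- tibble(
    time_s = c(dart_times, burst_times),
    peak_velocity_cm_s = c(dart_peaks, burst_peaks),
    kind = rep(c("dart", "shock_burst"),
               c(length(dart_times), length(burst_times)))
  )
  # snap to the sample grid, keeping clear of the trace endpoints
  ev$idx <- pmin(pmax(round(ev$time_s / sample_period) + 1, 3), n - 2)
  ev$time_s <- times[ev$idx]
  ev <- ev[order(ev$time_s), ]

  ## --- render pulses ---
  sigma <- params$dart_pulse_width / 4
  half <- ceiling(params$dart_pulse_width / sample_period)
  for (j in seq_len(nrow(ev))) {
    i0 <- ev$idx[j]
    span <- max(1, i0 - half):min(n, i0 + half)
    pulse <- ev$peak_velocity_cm_s[j] *
      exp(-((times[span] - ev$time_s[j])^2) / (2 * sigma^2))
    v[span] <- pmax(v[span], pulse)
  }

  freeze_bouts <- tibble(
    start_s = bounds[-length(bounds)][states == "freeze"],
    end_s = pmin(bounds[-1][states == "freeze"], total_s)
  )

  trace <- velocity_trace(v, animal_id = NA_character_,
                          session_id = attr(schedule, "session_id"),
                          sample_period = sample_period)
  truth <- structure(
    list(
      events = ev[, c("time_s", "peak_velocity_cm_s", "kind")],
      freeze_bouts = freeze_bouts,
      label = params$label,
      darter = is_darter_label(params$label)
    ),
    class = "ground_truth"
  )
  list(trace = trace, truth = truth)
}

cs_rates_for <- function(params, n_trials, session_id) {
  if (identical(session_id, "conditioning")) {
    params$cs_dart_rate_by_trial[seq_len(n_trials)]
  } else {
    # tone-alone sessions reuse the terminal conditioning CS rate
    rep(params$cs_dart_rate_by_trial[12], n_trials)
  }
}

# partition [lo, hi) into maximal segments of constant dart rate: specified
# windows keep their own rate, everything else gets the baseline
flatten_rate_segments <- function(windows, lo, hi, base_rate) {
  if (is.null(windows) || nrow(windows) == 0) {
    return(tibble(start = lo, end = hi, rate = base_rate))
  }
  windows <- dplyr::arrange(windows, .data$start)
  out <- list()
  cur <- lo
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (w$start > cur) out[[length(out) + 1]] <- tibble(start = cur, end = w$start, rate = base_rate)
    out[[length(out) + 1]] <- tibble(start = max(w$start, lo), end = min(w$end, hi), rate = w$rate)
    cur <- max(cur, w$end)
  }
  if (cur < hi) out[[length(out) + 1]] <- tibble(start = cur, end = hi, rate = base_rate)
  res <- dplyr::bind_rows(out)
  res[res$end > res$start, ]
}

#' Simulate a full cohort across the three-day protocol
#'
#' Assigns each animal a Darter/Non-darter phenotype by an independent
#' Bernoulli draw per sex, then simulates the requested sessions for every
#' animal. Every random choice flows from seeds derived from the master seed
#' by a fixed arithmetic counter scheme over (sex, animal index, session), so
#' a given animal's traces are identical whatever the cohort size — cohorts
#' are reproducible under subsetting.
#'
#' @param n_female,n_male Animals per sex (positive integers).
#' @param darter_prop_female,darter_prop_male Planted Darter probability per
#'   sex, in `[0, 1]`. The study's realized proportions were 0.414 (females)
#'   and 0.107 (males).
#' @param seed Master integer seed.
#' @param sessions Character vector of sessions to simulate (default all
#'   three).
#' @param phenotypes Named list of [phenotype_params()] as produced by
#'   [default_phenotypes()].
#' @param sample_period Sampling interval in seconds (default `1/3.75`).
#' @return A `cohort_sim` list: `animals`, a tibble with one row per animal
#'   (`animal_id`, `sex`, `phenotype`, `darter`); and `runs`, a tibble with
#'   one row per animal-session holding `trace`, `schedule` and `truth` as
#'   list-columns.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(4, 4, 0.5, 0.1, seed = 11, sessions = "conditioning")
#' sim$animals
#' }
#' @export
simulate_cohort <- function(n_female, n_male,
                            darter_prop_female, darter_prop_male,
                            seed,
                            sessions = c("conditioning", "extinction",
                                         "extinction_test"),
                            phenotypes = default_phenotypes(),
                            sample_period = 1 / 3.75) {
  if (n_female <= 0 || n_male <= 0) abort("Animal counts must be positive.")
  if (any(c(darter_prop_female, darter_prop_male) < 0 |
            c(darter_prop_female, darter_prop_male) > 1)) {
    abort("Darter proportions must lie in [0, 1].")
  }
  sessions <- match.arg(sessions, c("conditioning", "extinction",
                                    "extinction_test"), several.ok = TRUE)

  animals <- dplyr::bind_rows(
    tibble(sex = "female", i = seq_len(n_female),
           animal_id = sprintf("F%03d", seq_len(n_female)),
           prop = darter_prop_female),
    tibble(sex = "male", i = seq_len(n_male),
           animal_id = sprintf("M%03d", seq_len(n_male)),
           prop = darter_prop_male)
  )
  animals$darter <- purrr::map2_lgl(animals$sex, animals$i, function(sex, i) {
    withr_seed(derive_seed(seed, sex, i, 0L),
               runif(1) < animals$prop[animals$sex == sex & animals$i == i])
  })
  animals$phenotype <- paste0(animals$sex, "_",
                              ifelse(animals$darter, "darter", "nondarter"))

  session_codes <- c(conditioning = 1L, extinction = 2L, extinction_test = 3L)
  runs <- tidyr::expand_grid(
    animals[, c("animal_id", "sex", "i", "phenotype")],
    session_id = sessions
  )
  sims <- purrr::pmap(runs, function(animal_id, sex, i, phenotype, session_id) {
    s <- derive_seed(seed, sex, i, session_codes[[session_id]])
    schedule <- build_schedule(session_id, seed = s)
    out <- simulate_animal(phenotypes[[phenotype]], schedule, seed = s + 1L,
                           sample_period = sample_period)
    attr(out$trace, "animal_id") <- animal_id
    list(trace = out$trace, schedule = schedule, truth = out$truth)
  })
  runs$trace <- purrr::map(sims, "trace")
  runs$schedule <- purrr::map(sims, "schedule")
  runs$truth <- purrr::map(sims, "truth")
  runs$i <- NULL

  structure(
    list(
      animals = animals[, c("animal_id", "sex", "phenotype", "darter")],
      runs = runs,
      seed = seed
    ),
    class = "cohort_sim"
  )
}

# fixed counter scheme: distinct (sex, animal, session) tuples map to
# distinct 31-bit seeds for any master seed below ~2e6
derive_seed <- function(master, sex, animal_index, session_index) {
  sex_code <- if (identical(sex, "female")) 0L else 1L
  as.integer((abs(master) * 1000003 + sex_code * 500009 +
                animal_index * 211 + session_index * 17) %% 2147483629) + 1L
}
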