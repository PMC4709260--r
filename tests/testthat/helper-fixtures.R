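# Shared fixtures: trace builders and an independent detector oracle.

# trace with narrow triangular pulses at the given times/heights over a flat
# floor, so each pulse is a strict local maximum at its nominal sample
pulse_trace <- function(peak_times, peak_heights, duration = 60,
                        period = 1 / 3.75, floor = 0,
                        animal_id = "test", session_id = "conditioning") {
  n <- round(duration / period) + 1
  times <- (seq_len(n) - 1) * period
  v <- rep(floor, n)
  for (j in seq_along(peak_times)) {
    i <- which.min(abs(times - peak_times[j]))
    v[i] <- max(v[i], peak_heights[j])
    for (off in c(-1, 1)) {
      k <- i + off
      if (k >= 1 && k <= n) v[k] <- max(v[k], peak_heights[j] * 0.4)
    }
  }
  velocity_trace(v, animal_id, session_id, sample_period = period)
}

# independent oracle for the canonical spacing policy: repeatedly take the
# highest remaining local maximum above threshold (earliest on ties) and
# discard every candidate closer than the minimum interval
oracle_detect <- function(trace, min_peak = 23.5, min_sep = 0.8) {
  v <- trace$velocity_cm_s
  t <- trace$time_s
  n <- length(v)
  cand <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1  # plateau scan
      if (j < n && v[j + 1] < v[i]) cand <- c(cand, i)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  cand <- cand[v[cand] >= min_peak]
  kept <- integer(0)
  while (length(cand) > 0) {
    best <- cand[order(-v[cand], t[cand])][1]
    kept <- c(kept, best)
    cand <- cand[abs(t[cand] - t[best]) >= min_sep]
    cand <- setdiff(cand, best)
  }
  sort(kept)
}

# random spiky trace for detector stress tests: smooth sub-threshold
# baseline with superimposed spikes, some adjacent
random_spiky_trace <- function(n, seed, period = 1 / 3.75) {
  set.seed(seed)
  v <- runif(n, 0, 20)
  n_spikes <- rpois(1, n / 40)
  at <- sample(2:(n - 1), min(n_spikes, n - 2))
  v[at] <- runif(length(at), 20, 60)
  velocity_trace(v, "rnd", "conditioning", sample_period = period)
}

# one-US-trial schedule with an explicit CS onset
single_trial_schedule <- function(cs_onset = 300, has_us = TRUE,
                                  session_id = "custom") {
  session_schedule(
    tibble::tibble(
      trial = 1L, cs_onset_s = cs_onset, cs_duration_s = 30,
      has_us = has_us, us_duration_s = if (has_us) 0.5 else 0
    ),
    session_id = session_id
  )
}
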