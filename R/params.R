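#' Detection parameters
#'
#' Thresholds for dart and freezing detection. The dart criteria are the
#' study's stated values: a velocity peak of at least 23.5 cm/s and at least
#' 0.8 s between retained peaks. Freezing is scored from the velocity trace as
#' sub-threshold immobility runs of at least 2 s; the 2.0 cm/s immobility
#' threshold is this package's convention (the original study scored freezing
#' with pixel-change software), so absolute freezing percentages are not
#' comparable across scoring methods.
#'
#' @param min_peak_velocity Minimum dart peak velocity, cm/s (default 23.5).
#' @param min_interpeak_interval Minimum separation between retained peaks,
#'   seconds (default 0.8).
#' @param freezing_velocity_threshold Immobility threshold, cm/s (default 2).
#' @param min_freeze_bout Minimum freezing bout duration, seconds (default 2).
#'
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_peak_velocity = 23.5,
                             min_interpeak_interval = 0.8,
                             freezing_velocity_threshold = 2,
                             min_freeze_bout = 2) {
  if (!(min_peak_velocity > freezing_velocity_threshold &&
        freezing_velocity_threshold > 0)) {
    abort("Require min_peak_velocity > freezing_velocity_threshold > 0.")
  }
  if (min_interpeak_interval <= 0) abort("min_interpeak_interval must be > 0.")
  if (min_freeze_bout <= 0) abort("min_freeze_bout must be > 0.")
  structure(
    list(
      min_peak_velocity = min_peak_velocity,
      min_interpeak_interval = min_interpeak_interval,
      freezing_velocity_threshold = freezing_velocity_threshold,
      min_freeze_bout = min_freeze_bout
    ),
    class = "detection_params"
  )
}

#' Phenotype parameters for the synthetic-cohort simulator
#'
#' Describes one behavioral phenotype as a generative model: a two-state
#' freeze/move semi-Markov background (exponential dwell times; log-normal
#' speeds while moving, near-zero jitter while frozen), dart events from an
#' inhomogeneous Poisson process whose rate depends on the trial epoch, and a
#' guaranteed shock-evoked velocity burst on every US.
#'
#' `cs_dart_rate_by_trial` has one entry per conditioning trial (length 12);
#' habituation entries (trials 1-5) equal the baseline rate, and for
#' `*_darter` phenotypes the entries over trials 6-12 must be non-decreasing
#' (conditioned darting strengthens as tone-shock pairings progress).
#'
#' @param label Phenotype label; darter phenotypes must end in `"_darter"`
#'   (not `"_nondarter"`).
#' @param baseline_speed_mean,baseline_speed_sd Moving-state speed moments,
#'   cm/s (log-normal).
#' @param freeze_bout_mean,move_bout_mean Mean dwell times, seconds.
#' @param baseline_dart_rate Dart rate outside CS/post-shock windows,
#'   darts/min.
#' @param cs_dart_rate_by_trial Dart rate during each conditioning CS,
#'   darts/min (length 12). For extinction sessions the last entry is reused
#'   for every CS.
#' @param post_shock_dart_rate Dart rate during 30-s post-shock windows,
#'   darts/min.
#' @param shock_burst_peak_mean,shock_burst_peak_sd Shock-burst peak velocity
#'   distribution, cm/s; a mean of 0 disables shock bursts.
#' @param dart_pulse_peak_mean,dart_pulse_peak_sd Dart pulse peak velocity
#'   distribution, cm/s; the mean must exceed the 23.5 cm/s detection
#'   threshold.
#' @param dart_pulse_width Full width of the rendered dart pulse, seconds;
#'   must be below the 0.8 s interpeak interval.
#'
#' @return A `phenotype_params` list.
#' @seealso [default_phenotypes()]
#' @export
phenotype_params <- function(label,
                             baseline_speed_mean = 4,
                             baseline_speed_sd = 1.2,
                             freeze_bout_mean = 8,
                             move_bout_mean = 12,
                             baseline_dart_rate = 0.002,
                             cs_dart_rate_by_trial = rep(baseline_dart_rate, 12),
                             post_shock_dart_rate = 0.5,
                             shock_burst_peak_mean = 55,
                             shock_burst_peak_sd = 8,
                             dart_pulse_peak_mean = 35,
                             dart_pulse_peak_sd = 4,
                             dart_pulse_width = 0.5) {
  rates <- c(baseline_dart_rate, cs_dart_rate_by_trial, post_shock_dart_rate)
  if (any(rates < 0)) abort("All dart rates must be >= 0.")
  if (length(cs_dart_rate_by_trial) != 12) {
    abort("cs_dart_rate_by_trial must have length 12 (one entry per conditioning trial).")
  }
  if (dart_pulse_peak_mean <= 23.5) {
    abort("dart_pulse_peak_mean must exceed the 23.5 cm/s detection threshold.")
  }
  if (dart_pulse_width >= 0.8) {
    abort("dart_pulse_width must be below the 0.8 s minimum interpeak interval.")
  }
  if (is_darter_label(label)) {
    ramp <- cs_dart_rate_by_trial[6:12]
    if (is.unsorted(ramp)) {
      abort("For *_darter phenotypes, cs_dart_rate_by_trial must be non-decreasing over trials 6-12.")
    }
  }
  structure(
    list(
      label = label,
      baseline_speed_mean = baseline_speed_mean,
      baseline_speed_sd = baseline_speed_sd,
      freeze_bout_mean = freeze_bout_mean,
      move_bout_mean = move_bout_mean,
      baseline_dart_rate = baseline_dart_rate,
      cs_dart_rate_by_trial = cs_dart_rate_by_trial,
      post_shock_dart_rate = post_shock_dart_rate,
      shock_burst_peak_mean = shock_burst_peak_mean,
      shock_burst_peak_sd = shock_burst_peak_sd,
      dart_pulse_peak_mean = dart_pulse_peak_mean,
      dart_pulse_peak_sd = dart_pulse_peak_sd,
      dart_pulse_width = dart_pulse_width
    ),
    class = "phenotype_params"
  )
}

is_darter_label <- function(label) {
  grepl("(^|_)darter$", label) && !grepl("nondarter$", label)
}

#' Default phenotype parameter sets
#'
#' Four phenotypes crossing sex with Darter status. Darters ramp their CS
#' dart rate from 1 dart/min on the first tone-shock pairing (trial 6) to 6
#' darts/min on the last (trial 12), reaching at least 4 darts/min by trial 8
#' — the first trial read by the Darter criterion — and dart at 3 darts/min
#' in post-shock windows. Non-darters keep the near-zero baseline rate during
#' the CS. Both phenotypes produce a shock burst on every US (both sexes dart
#' in response to the shock itself); the parameter sets are shared across
#' sexes, sex differences entering through the cohort's phenotype
#' proportions.
#'
#' @return Named list of [phenotype_params()], keyed by
#'   `female_darter`, `female_nondarter`, `male_darter`, `male_nondarter`.
#' @export
default_phenotypes <- function() {
  darter_cs <- c(rep(0.002, 5), 1, 2, 4, 4.5, 5, 5.5, 6)
  darter <- function(label) {
    phenotype_params(
      label = label,
      cs_dart_rate_by_trial = darter_cs,
      post_shock_dart_rate = 3
    )
  }
  nondarter <- function(label) phenotype_params(label = label)
  list(
    female_darter = darter("female_darter"),
    female_nondarter = nondarter("female_nondarter"),
    male_darter = darter("male_darter"),
    male_nondarter = nondarter("male_nondarter")
  )
}
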