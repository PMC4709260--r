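#' Classify an animal as Darter or Non-darter
#'
#' An animal qualifies as a Darter when it shows at least one dart during the
#' tone (CS epoch) of conditioning trials 8-12 — the third through seventh
#' tone-shock pairing, the period in which conditioned responding is
#' established. Darts during habituation tones (trials 1-5), trials 6-7, the
#' shock-response or post-shock windows, the pre-CS period or inter-trial
#' intervals do not qualify.
#'
#' @param conditioning_events Labeled events (from [assign_events()]) of one
#'   animal's conditioning session.
#' @param trials Qualifying trial indices (default `8:12`).
#' @return `TRUE` for a Darter.
#' @export
classify_darter <- function(conditioning_events, trials = 8:12) {
  sid <- unique(stats::na.omit(conditioning_events$session_id))
  if (length(sid) > 0 && !identical(sid, "conditioning")) {
    abort("Darter status is defined on the conditioning session only.")
  }
  if (nrow(conditioning_events) > 0 && all(is.na(conditioning_events$epoch))) {
    abort("Events must be labeled with assign_events() first.")
  }
  any(conditioning_events$epoch == "cs" &
        !is.na(conditioning_events$trial_index) &
        conditioning_events$trial_index %in% trials,
      na.rm = TRUE)
}

#' Flag outlier animals by total dart count
#'
#' Flags animals whose conditioning total dart count exceeds the stratum mean
#' by more than `k` standard deviations (the study removed one male at 6 SD).
#' Mean and SD are computed including the candidate; a zero-SD stratum
#' excludes nobody. Flagged rows stay in the table, marked `excluded` with a
#' reason, and are omitted from all downstream statistics.
#'
#' @param cohort A cohort tibble with columns `animal_id`, `sex` and
#'   `total_dart_count` (conditioning session).
#' @param k SD multiplier (default 6).
#' @param grouping `"within_sex"` (default) or `"whole_cohort"`: the stratum
#'   over which mean and SD are taken.
#' @return The cohort tibble with `excluded` (logical) and
#'   `exclusion_reason` columns filled in.
#' @export
exclude_outliers <- function(cohort, k = 6,
                             grouping = c("within_sex", "whole_cohort")) {
  grouping <- match.arg(grouping)
  if (!"total_dart_count" %in% names(cohort)) {
    abort("`cohort` must contain a conditioning `total_dart_count` column.")
  }
  grp <- if (grouping == "within_sex") cohort$sex else rep("all", nrow(cohort))
  if (any(table(grp) < 3)) {
    abort("Each outlier stratum needs at least 3 animals.")
  }
  out <- cohort
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  for (g in unique(grp)) {
    rows <- which(grp == g)
    m <- mean(cohort$total_dart_count[rows])
    s <- sd(cohort$total_dart_count[rows])
    if (!is.finite(s) || s == 0 || !is.finite(k)) next
    bad <- rows[cohort$total_dart_count[rows] > m + k * s]
    out$excluded[bad] <- TRUE
    out$exclusion_reason[bad] <- sprintf(
      "total dart count > mean + %g SD of %s stratum", k, g
    )
  }
  out
}

#' Sex-by-Darter contingency table
#'
#' Counts Darters and Non-darters by sex among non-excluded animals, the
#' input to the chi-square test of independence.
#'
#' @param cohort A cohort tibble with `sex`, `darter` and (optionally)
#'   `excluded` columns.
#' @return A 2x2 integer matrix, rows `female`/`male`, columns
#'   `darter`/`nondarter`.
#' @export
darter_contingency <- function(cohort) {
  if (nrow(cohort) == 0) abort("Empty cohort.")
  if ("excluded" %in% names(cohort)) {
    cohort <- dplyr::filter(cohort, !.data$excluded)
  }
  sexes <- sort(unique(cohort$sex))
  if (!setequal(sexes, c("female", "male"))) {
    abort("Cohort must contain both sexes for the sex x Darter contingency table.")
  }
  tab <- matrix(0L, 2, 2, dimnames = list(sex = c("female", "male"),
                                          status = c("darter", "nondarter")))
  for (sx in c("female", "male")) {
    tab[sx, "darter"] <- sum(cohort$sex == sx & cohort$darter)
    tab[sx, "nondarter"] <- sum(cohort$sex == sx & !cohort$darter)
  }
  tab
}

#' Assemble the animal-level cohort table from a simulated or measured cohort
#'
#' Runs detection, epoch assignment, metric computation and Darter
#' classification over every conditioning run and joins session-level
#' summaries into one row per animal. This is the table the statistics stage
#' consumes.
#'
#' @param runs A tibble with one row per animal-session and list-columns
#'   `trace`, `schedule` (as in the `runs` element of [simulate_cohort()])
#'   plus `animal_id`, `sex`, `session_id` columns.
#' @param params A [detection_params()].
#' @param exclusion_k SD multiplier for [exclude_outliers()] (default 6);
#'   `Inf` disables exclusion.
#' @param grouping Outlier stratum, as in [exclude_outliers()].
#' @param darter_trials Qualifying trials for [classify_darter()].
#' @return A tibble with one row per animal: `animal_id`, `sex`, `darter`,
#'   `excluded`, `exclusion_reason`, and per-session summary columns
#'   (`<session>_pre_cs_dart_rate`, `<session>_total_dart_count`,
#'   `<session>_mean_shock_velocity`), with `total_dart_count` aliasing the
#'   conditioning count.
#' @export
build_cohort_table <- function(runs, params = detection_params(),
                               exclusion_k = 6,
                               grouping = c("within_sex", "whole_cohort"),
                               darter_trials = 8:12) {
  grouping <- match.arg(grouping)
  per_run <- purrr::pmap(
    runs[, c("animal_id", "session_id", "trace", "schedule")],
    function(animal_id, session_id, trace, schedule) {
      epochs <- build_epochs(schedule)
      events <- assign_events(detect_darts(trace, params), epochs)
      bouts <- score_freezing(trace, params)
      metrics <- compute_metrics(events, bouts, trace, epochs)
      tibble(
        animal_id = animal_id, session_id = session_id,
        darter = if (session_id == "conditioning") {
          classify_darter(events, trials = darter_trials)
        } else NA,
        pre_cs_dart_rate = metrics$session$pre_cs_dart_rate,
        session_dart_count = metrics$session$total_dart_count,
        mean_shock_velocity = metrics$session$mean_shock_response_velocity
      )
    }
  )
  per_run <- dplyr::bind_rows(per_run)
  wide <- tidyr::pivot_wider(
    per_run,
    id_cols = "animal_id",
    names_from = "session_id",
    values_from = c("pre_cs_dart_rate", "session_dart_count",
                    "mean_shock_velocity"),
    names_glue = "{session_id}_{.value}"
  )
  status <- dplyr::summarise(
    dplyr::group_by(per_run, .data$animal_id),
    darter = any(.data$darter, na.rm = TRUE), .groups = "drop"
  )
  meta <- dplyr::distinct(runs[, c("animal_id", "sex")])
  cohort <- dplyr::left_join(meta, status, by = "animal_id")
  cohort <- dplyr::left_join(cohort, wide, by = "animal_id")
  cohort$total_dart_count <- cohort$conditioning_session_dart_count
  exclude_outliers(cohort, k = exclusion_k, grouping = grouping)
}
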