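#' Pipeline configuration
#'
#' Bundles every tunable of the simulate - detect - analyze - classify -
#' stats pipeline. Defaults equal the study's stated values wherever one
#' exists: 23.5 cm/s dart threshold, 0.8 s interpeak interval, 2 s minimum
#' freezing bout, 60/30/5/30-s epochs, the CS 8-12 Darter criterion and the
#' 6-SD outlier rule.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"files"` (read
#'   previously written trace CSVs and schedule JSONs from `input_dir`).
#' @param n_female,n_male Simulated animals per sex.
#' @param darter_prop_female,darter_prop_male Planted Darter proportions.
#' @param seed Master seed.
#' @param sessions Sessions to simulate/analyze.
#' @param detection A [detection_params()].
#' @param shock_summary Per-trial shock-velocity summary entering the
#'   session mean (`"mean"` or `"max"`), see [compute_metrics()].
#' @param exclusion_k SD multiplier for outlier exclusion (default 6).
#' @param exclusion_grouping `"within_sex"` or `"whole_cohort"`.
#' @param darter_trials Trial indices read by the Darter criterion.
#' @param write_traces Also write every simulated trace CSV (off by default;
#'   traces are large and reproducible from the manifest seed).
#' @param input_dir Directory of input files for `mode = "files"`.
#' @return A `darting_config` list.
#' @export
darting_config <- function(mode = c("simulate", "files"),
                           n_female = 58, n_male = 56,
                           darter_prop_female = 0.414,
                           darter_prop_male = 0.107,
                           seed = 11,
                           sessions = c("conditioning", "extinction",
                                        "extinction_test"),
                           detection = detection_params(),
                           shock_summary = c("mean", "max"),
                           exclusion_k = 6,
                           exclusion_grouping = c("within_sex", "whole_cohort"),
                           darter_trials = 8:12,
                           write_traces = FALSE,
                           input_dir = NULL) {
  structure(
    list(
      mode = match.arg(mode),
      n_female = n_female, n_male = n_male,
      darter_prop_female = darter_prop_female,
      darter_prop_male = darter_prop_male,
      seed = seed, sessions = sessions, detection = detection,
      shock_summary = match.arg(shock_summary),
      exclusion_k = exclusion_k,
      exclusion_grouping = match.arg(exclusion_grouping),
      darter_trials = darter_trials,
      write_traces = write_traces, input_dir = input_dir
    ),
    class = "darting_config"
  )
}

#' Run the full darting pipeline
#'
#' Simulates (or loads) a cohort, detects darts and freezing, computes
#' per-trial metrics, classifies Darters, applies outlier exclusion, runs
#' the group statistics and writes everything under `output_dir`: per
#' animal-session event and bout CSVs (`events/`, `bouts/`), a combined
#' trial-metrics CSV, the cohort table, sex-averaged peri-CS histogram
#' matrices, a statistics report CSV and a `manifest.json` recording the
#' configuration, seed and package version. Reruns with the same
#' configuration reproduce all outputs byte-identically. An existing
#' manifest in `output_dir` aborts the run unless `overwrite = TRUE`.
#'
#' @param config A [darting_config()].
#' @param output_dir Output directory (created if needed).
#' @param overwrite Allow writing into a directory holding a previous run.
#' @param quiet Suppress stage-boundary messages.
#' @return `output_dir`, invisibly; the written files are the result.
#' @export
run_darting_pipeline <- function(config = darting_config(), output_dir,
                                 overwrite = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "darting_config"))
  manifest_path <- file.path(output_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    abort("Output directory holds a previous run; set overwrite = TRUE to replace it.")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "events"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "bouts"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (config$mode == "simulate") {
    say("Simulating cohort: %d female + %d male animals, sessions: %s",
        config$n_female, config$n_male, paste(config$sessions, collapse = ", "))
    sim <- simulate_cohort(config$n_female, config$n_male,
                           config$darter_prop_female, config$darter_prop_male,
                           seed = config$seed, sessions = config$sessions)
    runs <- sim$runs
  } else {
    runs <- load_run_files(config$input_dir, config$sessions)
  }

  if (isTRUE(config$write_traces)) {
    dir.create(file.path(output_dir, "traces"), showWarnings = FALSE)
    purrr::pwalk(runs[, c("animal_id", "session_id", "trace")],
                 function(animal_id, session_id, trace) {
      write_trace(trace, file.path(output_dir, "traces",
                                   paste0(animal_id, "_", session_id, ".csv")))
    })
  }

  say("Detecting darts and freezing in %d traces", nrow(runs))
  analyzed <- purrr::pmap(
    runs[, c("animal_id", "session_id", "trace", "schedule")],
    function(animal_id, session_id, trace, schedule) {
      epochs <- build_epochs(schedule)
      events <- assign_events(detect_darts(trace, config$detection), epochs)
      bouts <- score_freezing(trace, config$detection)
      metrics <- compute_metrics(events, bouts, trace, epochs,
                                 shock_summary = config$shock_summary)
      write_events(events, file.path(output_dir, "events",
                                     paste0(animal_id, "_", session_id, ".csv")))
      write_bouts(bouts, file.path(output_dir, "bouts",
                                   paste0(animal_id, "_", session_id, ".csv")))
      list(animal_id = animal_id, session_id = session_id,
           events = events, metrics = metrics,
           histogram = if (session_id == "conditioning") {
             peri_cs_histogram(events, schedule)
           })
    }
  )
  say("Detected %d dart events in total",
      sum(purrr::map_int(analyzed, ~ nrow(.x$events))))

  trial_metrics <- purrr::map_dfr(analyzed, ~ .x$metrics$trial)
  session_metrics <- purrr::map_dfr(analyzed, ~ .x$metrics$session)
  readr::write_csv(trial_metrics, file.path(output_dir, "trial_metrics.csv"))
  readr::write_csv(session_metrics, file.path(output_dir, "session_metrics.csv"))

  say("Classifying Darters and applying the %g-SD exclusion rule",
      config$exclusion_k)
  cohort <- build_cohort_table(runs, params = config$detection,
                               exclusion_k = config$exclusion_k,
                               grouping = config$exclusion_grouping,
                               darter_trials = config$darter_trials)
  readr::write_csv(cohort, file.path(output_dir, "cohort.csv"))
  say("Cohort: %d animals, %d Darters, %d excluded",
      nrow(cohort), sum(cohort$darter), sum(cohort$excluded))

  # sex-averaged peri-CS histograms (conditioning)
  for (sx in unique(runs$sex)) {
    ids <- runs$animal_id[runs$sex == sx & runs$session_id == "conditioning"]
    hists <- purrr::keep(analyzed, ~ .x$animal_id %in% ids &&
                           .x$session_id == "conditioning")
    if (length(hists) > 0) {
      avg <- average_histograms(purrr::map(hists, "histogram"))
      utils::write.csv(unclass(avg),
                       file.path(output_dir, paste0("peri_cs_histogram_", sx, ".csv")))
    }
  }

  say("Running group statistics")
  stats_tbl <- pipeline_statistics(cohort, trial_metrics)
  readr::write_csv(stats_tbl, file.path(output_dir, "statistics.csv"))

  manifest <- list(
    package = "dartscore",
    version = as.character(packageVersion("dartscore")),
    config = config_as_list(config),
    n_animals = nrow(cohort),
    n_excluded = sum(cohort$excluded),
    outputs = sort(c("cohort.csv", "trial_metrics.csv", "session_metrics.csv",
                     "statistics.csv"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$detection <- unclass(out$detection)
  out
}

# statistics report: the pipeline's standing comparisons, degenerate cases
# reported as rows rather than errors
pipeline_statistics <- function(cohort, trial_metrics) {
  keep <- cohort[!cohort$excluded, ]
  rows <- list()
  add <- function(comparison, test) {
    rows[[length(rows) + 1]] <<- dplyr::mutate(tidy(test),
                                               comparison = comparison,
                                               .before = 1)
  }
  note <- function(comparison, msg) {
    rows[[length(rows) + 1]] <<- tibble(
      comparison = comparison, test = "skipped", effect = msg,
      statistic = NA_real_, df = NA_real_, df2 = NA_real_, p_value = NA_real_
    )
  }

  tab <- tryCatch(darter_contingency(keep), error = function(e) e)
  if (inherits(tab, "error")) {
    note("darter_by_sex", conditionMessage(tab))
  } else if (any(colSums(tab) == 0)) {
    note("darter_by_sex", "degenerate table: a Darter status is empty")
  } else {
    add("darter_by_sex", chi_square_independence(tab))
  }

  for (sx in c("female", "male")) {
    grp <- keep[keep$sex == sx, ]
    if (sum(grp$darter) >= 2 && sum(!grp$darter) >= 2) {
      add(paste0(sx, "_pre_cs_darter_vs_nondarter"),
          mann_whitney_u(grp$conditioning_pre_cs_dart_rate[grp$darter],
                         grp$conditioning_pre_cs_dart_rate[!grp$darter]))
      long <- dplyr::inner_join(
        trial_metrics[trial_metrics$session_id == "conditioning", ],
        grp[, c("animal_id", "darter")], by = "animal_id"
      )
      fit <- mixed_anova(long, value = "cs_dart_rate", group = "darter",
                         trial = "trial", subject = "animal_id")
      tb <- tidy(fit)
      for (eff in c("group", "trial", "group_x_trial")) {
        r <- tb[tb$effect == eff, ]
        rows[[length(rows) + 1]] <- tibble(
          comparison = paste0(sx, "_cs_dart_rate_anova"),
          test = "mixed_anova", effect = eff, statistic = r$statistic,
          df = r$df, df2 = r$df_error, p_value = r$p_value
        )
      }
    } else {
      note(paste0(sx, "_darter_vs_nondarter"),
           "fewer than 2 animals in a Darter group")
    }
    if (nrow(grp) >= 3 && sd(grp$total_dart_count) > 0 &&
          sd(grp$conditioning_mean_shock_velocity) > 0) {
      add(paste0(sx, "_shock_velocity_vs_dart_count"),
          pearson_r(grp$conditioning_mean_shock_velocity,
                    grp$total_dart_count))
    }
  }
  dplyr::bind_rows(rows)
}

# files mode: <animal>_<session>.csv traces, <animal>_<session>.json
# schedules and an animals.csv with animal_id,sex
load_run_files <- function(input_dir, sessions) {
  if (is.null(input_dir) || !dir.exists(input_dir)) {
    abort("mode = 'files' requires an existing `input_dir`.")
  }
  meta <- readr::read_csv(file.path(input_dir, "animals.csv"),
                          show_col_types = FALSE, progress = FALSE)
  runs <- tidyr::expand_grid(meta[, c("animal_id", "sex")],
                             session_id = sessions)
  runs$schedule <- purrr::map2(runs$animal_id, runs$session_id, function(a, s) {
    read_schedule(file.path(input_dir, paste0(a, "_", s, ".json")))
  })
  runs$trace <- purrr::pmap(runs[, c("animal_id", "session_id", "schedule")],
                            function(animal_id, session_id, schedule) {
    tr <- load_trace(file.path(input_dir,
                               paste0(animal_id, "_", session_id, ".csv")),
                     animal_id, session_id)
    check_trace_covers(tr, schedule)
    tr
  })
  runs
}
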