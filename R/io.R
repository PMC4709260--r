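#' Read and write dart events, freezing bouts and metrics as CSV
#'
#' One row per event/bout, one animal-session per file, stable column order,
#' full numeric precision: a write followed by the corresponding read
#' reproduces the input. Event columns:
#' `animal_id,session_id,time_s,peak_velocity_cm_s,trial_index,epoch`; bout
#' columns: `animal_id,session_id,start_s,end_s`.
#'
#' @param events Event tibble as produced by [detect_darts()] /
#'   [assign_events()].
#' @param bouts Bout tibble as produced by [score_freezing()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the tibble.
#' @export
write_events <- function(events, path) {
  cols <- c("animal_id", "session_id", "time_s", "peak_velocity_cm_s",
            "trial_index", "epoch")
  check_single_animal_session(events)
  readr::write_csv(events[, cols], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    session_id = readr::col_character(),
                    time_s = readr::col_double(),
                    peak_velocity_cm_s = readr::col_double(),
                    trial_index = readr::col_integer(),
                    epoch = readr::col_character()
                  ))
}

#' @rdname write_events
#' @export
write_bouts <- function(bouts, path) {
  check_single_animal_session(bouts)
  readr::write_csv(bouts[, c("animal_id", "session_id", "start_s", "end_s")],
                   path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_bouts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    session_id = readr::col_character(),
                    start_s = readr::col_double(),
                    end_s = readr::col_double()
                  ))
}

#' @rdname write_events
#' @param metrics An `animal_metrics` object from [compute_metrics()].
#' @export
write_metrics <- function(metrics, path) {
  joined <- dplyr::left_join(metrics$trial, metrics$session,
                             by = c("animal_id", "session_id"))
  readr::write_csv(joined, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

check_single_animal_session <- function(x) {
  key <- unique(paste(x$animal_id, x$session_id))
  if (length(key) > 1) {
    abort("single animal-session per file: rows mix animal/session ids.")
  }
  invisible(x)
}
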