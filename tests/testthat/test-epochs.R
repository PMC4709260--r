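test_that("epoch windows follow the 60/30/5/30-s layout", {
  sched <- build_schedule("conditioning", seed = 6)
  ep <- build_epochs(sched)
  pre <- ep[ep$epoch == "pre_cs", ]
  expect_equal(nrow(pre), 1)
  expect_equal(c(pre$start_s, pre$end_s),
               sched$cs_onset_s[1] + c(-60, 0))
  expect_equal(sum(ep$epoch == "cs"), 12)
  expect_equal(sum(ep$epoch == "shock_response"), 7)
  expect_equal(sum(ep$epoch == "post_shock"), 7)

  # worked example: CS at 300 with a co-terminating 0.5-s US
  ep1 <- build_epochs(single_trial_schedule(cs_onset = 300))
  sh <- ep1[ep1$epoch == "shock_response", ]
  expect_equal(c(sh$start_s, sh$end_s), c(329.5, 334.5))
  ps <- ep1[ep1$epoch == "post_shock", ]
  expect_equal(c(ps$start_s, ps$end_s), c(334.5, 364.5))

  ext <- build_epochs(build_schedule("extinction", seed = 6))
  expect_equal(sum(ext$epoch %in% c("shock_response", "post_shock")), 0)

  too_early <- session_schedule(tibble::tibble(
    trial = 1L, cs_onset_s = 40, cs_duration_s = 30,
    has_us = FALSE, us_duration_s = 0
  ), acclimation_s = 10)
  expect_error(build_epochs(too_early), "pre-CS")
})

test_that("events are assigned to epochs with shock-response precedence", {
  sched <- single_trial_schedule(cs_onset = 300)
  ep <- build_epochs(sched)
  ev <- tibble::tibble(
    animal_id = "r1", session_id = "custom",
    time_s = c(100, 250, 305, 329.7, 340, 380),
    peak_velocity_cm_s = 30, trial_index = NA_integer_, epoch = NA_character_
  )
  lab <- assign_events(ev, ep)
  expect_equal(lab$epoch,
               c("acclimation", "pre_cs", "cs", "shock_response",
                 "post_shock", "iti"))
  # 329.7 is inside the CS's final 0.5 s but the shock window wins
  expect_equal(lab$trial_index,
               c(NA_integer_, NA_integer_, 1L, 1L, 1L, NA_integer_))

  beyond <- ev
  beyond$time_s[1] <- 1e6
  expect_error(assign_events(beyond, ep), "beyond the session extent")
})

test_that("metric arithmetic: darts/min, shock maxima, freezing", {
  sched <- single_trial_schedule(cs_onset = 300)
  ep <- build_epochs(sched)
  n <- ceiling(session_duration(sched) * 3.75) + 1
  v <- rep(0, n)
  tr <- velocity_trace(v, "r1", "custom")
  # plant shock-window samples {10, 50, 30}
  i <- which(tr$time_s >= 329.5 & tr$time_s < 334.5)[1:3]
  tr$velocity_cm_s[i] <- c(10, 50, 30)
  ev <- tibble::tibble(
    animal_id = "r1", session_id = "custom",
    time_s = c(305, 315), peak_velocity_cm_s = c(30, 40),
    trial_index = NA_integer_, epoch = NA_character_
  )
  lab <- assign_events(ev, ep)
  bouts <- tibble::tibble(animal_id = "r1", session_id = "custom",
                          start_s = 310, end_s = 325)
  m <- compute_metrics(lab, bouts, tr, ep)
  expect_equal(m$trial$cs_dart_rate, 4)          # 2 darts in 30 s
  expect_equal(m$trial$cs_freezing, 50)          # 15 of 30 s
  expect_equal(m$trial$shock_max_velocity, 50)
  expect_equal(m$session$pre_cs_dart_rate, 0)
  expect_equal(m$session$total_dart_count, 2)
  expect_equal(glance(m), m$session)
  expect_equal(tidy(m), m$trial)
})

test_that("dart counts are conserved across epoch labels", {
  for (seed in c(3, 11)) {
    sched <- build_schedule("conditioning", seed = seed)
    sim <- simulate_animal(default_phenotypes()$female_darter, sched,
                           seed = seed + 100)
    ep <- build_epochs(sched)
    lab <- assign_events(detect_darts(sim$trace), ep)
    bouts <- score_freezing(sim$trace)
    m <- compute_metrics(lab, bouts, sim$trace, ep)
    expect_equal(m$session$total_dart_count, sum(table(lab$epoch)))
    # rate x window-minutes recovers integer counts for every CS window
    counts <- m$trial$cs_dart_rate * 0.5
    expect_equal(counts, round(counts))
    expect_equal(sum(counts),
                 sum(lab$epoch == "cs"))
  }
})

test_that("peri-CS histograms bin darts at darts/min", {
  sched <- build_schedule("conditioning", seed = 6)
  empty <- tibble::tibble(
    animal_id = character(), session_id = character(), time_s = numeric(),
    peak_velocity_cm_s = numeric(), trial_index = integer(), epoch = character()
  )
  h0 <- peri_cs_histogram(empty, sched)
  expect_equal(dim(h0), c(12, 26))
  expect_true(all(h0 == 0))

  one <- empty
  one[1, ] <- list("r1", "conditioning", sched$cs_onset_s[6] + 1, 30, NA_integer_,
                   NA_character_)
  h1 <- peri_cs_histogram(one, sched)
  expect_equal(unname(h1[6, "0"]), 15)  # 1 dart / (4/60) min
  expect_equal(sum(h1), 15)

  # an event exactly on a bin edge belongs to the later bin
  edge <- empty
  edge[1, ] <- list("r1", "conditioning", sched$cs_onset_s[6] + 4, 30,
                    NA_integer_, NA_character_)
  h2 <- peri_cs_histogram(edge, sched)
  expect_equal(unname(h2[6, "4"]), 15)
  expect_equal(unname(h2[6, "0"]), 0)

  expect_error(peri_cs_histogram(empty, sched, bin_width = 0), "bin_width")
})

test_that("histogram marginals match CS epoch counts when bins tile the CS", {
  sched <- build_schedule("extinction", seed = 8)
  sim <- simulate_animal(default_phenotypes()$female_darter, sched, seed = 71)
  ev <- assign_events(detect_darts(sim$trace), build_epochs(sched))
  h <- peri_cs_histogram(ev, sched, bin_width = 5, span = c(-30, 70))
  cs_bins <- as.numeric(colnames(h)) >= 0 & as.numeric(colnames(h)) < 30
  counts_from_hist <- rowSums(h[, cs_bins, drop = FALSE]) * 5 / 60
  counts_from_epochs <- purrr::map_dbl(sched$trial, function(tr) {
    sum(ev$epoch == "cs" & !is.na(ev$trial_index) & ev$trial_index == tr)
  })
  expect_equal(unname(counts_from_hist), counts_from_epochs)

  # cohort averaging is element-wise
  h2 <- peri_cs_histogram(ev[0, ], sched, bin_width = 5, span = c(-30, 70))
  avg <- average_histograms(list(h, h2))
  expect_equal(unclass(avg), unclass(h) / 2, ignore_attr = TRUE)
})
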