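test_that("simulation is deterministic under a fixed seed", {
  sched <- build_schedule("conditioning", seed = 4)
  p <- default_phenotypes()$female_darter
  a <- simulate_animal(p, sched, seed = 9)
  b <- simulate_animal(p, sched, seed = 9)
  expect_identical(a$trace$velocity_cm_s, b$trace$velocity_cm_s)
  expect_identical(a$truth$events, b$truth$events)
  c <- simulate_animal(p, sched, seed = 10)
  expect_false(identical(a$trace$velocity_cm_s, c$trace$velocity_cm_s))
  expect_error(simulate_animal(p, sched, seed = NULL), "seed")
})

test_that("zero dart rates and disabled shock bursts give a quiet trace", {
  sched <- build_schedule("conditioning", seed = 4)
  quiet <- phenotype_params(
    "female_nondarter", baseline_dart_rate = 0,
    cs_dart_rate_by_trial = rep(0, 12), post_shock_dart_rate = 0,
    shock_burst_peak_mean = 0
  )
  sim <- simulate_animal(quiet, sched, seed = 21)
  expect_equal(nrow(sim$truth$events), 0)
  expect_lt(max(sim$trace$velocity_cm_s), 23.5)
  expect_equal(nrow(detect_darts(sim$trace)), 0)
})

test_that("planted events respect the detector's peak and spacing rules", {
  sched <- build_schedule("conditioning", seed = 4)
  sim <- simulate_animal(default_phenotypes()$female_darter, sched, seed = 7)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$peak_velocity_cm_s >= 23.5))
  expect_true(all(diff(sort(ev$time_s)) >= 0.8))
  # every planted event's sample is a strict local maximum of the trace
  idx <- match(round(ev$time_s, 9), round(sim$trace$time_s, 9))
  v <- sim$trace$velocity_cm_s
  expect_true(all(v[idx] > v[idx - 1] & v[idx] > v[idx + 1]))
})

test_that("the detector recovers planted events exactly across seeds", {
  p <- default_phenotypes()
  labels <- rep(c("female_darter", "male_nondarter"), length.out = 25)
  for (seed in seq_along(labels)) {
    sched <- build_schedule("conditioning", seed = seed)
    sim <- simulate_animal(p[[labels[seed]]], sched, seed = seed * 13)
    ev <- detect_darts(sim$trace)
    expect_equal(ev$time_s, sort(sim$truth$events$time_s))
  }
})

test_that("planted dart counts per CS window follow the specified Poisson rate", {
  # 50 tone-alone sessions x 20 CS windows = 1000 windows at 1 dart/min
  # (low enough that the refractory thinning of planted darts is negligible)
  p <- phenotype_params("rate_check_nondarter",
                        cs_dart_rate_by_trial = c(rep(0.002, 11), 1),
                        shock_burst_peak_mean = 0)
  counts <- integer(0)
  for (seed in 1:50) {
    sched <- build_schedule("extinction", seed = seed)
    sim <- simulate_animal(p, sched, seed = seed + 500)
    for (i in seq_len(nrow(sched))) {
      lo <- sched$cs_onset_s[i]
      hi <- lo + sched$cs_duration_s[i]
      counts <- c(counts, sum(sim$truth$events$time_s >= lo &
                                sim$truth$events$time_s < hi))
    }
  }
  lambda <- 1 * 30 / 60
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts >= 2))
  prob <- c(dpois(0:1, lambda), ppois(1, lambda, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = prob))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohorts assign phenotypes per sex and are subset-reproducible", {
  sim0 <- simulate_cohort(10, 10, 0, 0, seed = 1, sessions = "conditioning")
  expect_equal(sum(sim0$animals$darter), 0)
  expect_equal(nrow(sim0$animals), 20)

  sim_small <- simulate_cohort(3, 3, 0.5, 0.5, seed = 2,
                               sessions = "conditioning")
  sim_big <- simulate_cohort(6, 6, 0.5, 0.5, seed = 2,
                             sessions = "conditioning")
  tr_small <- sim_small$runs$trace[[which(sim_small$runs$animal_id == "F003")]]
  tr_big <- sim_big$runs$trace[[which(sim_big$runs$animal_id == "F003")]]
  expect_identical(tr_small$velocity_cm_s, tr_big$velocity_cm_s)
  expect_identical(
    sim_small$animals$darter[sim_small$animals$animal_id == "F003"],
    sim_big$animals$darter[sim_big$animals$animal_id == "F003"]
  )

  full <- simulate_cohort(2, 2, 1, 1, seed = 3)
  expect_equal(nrow(full$runs), 4 * 3)
  expect_setequal(unique(full$runs$session_id),
                  c("conditioning", "extinction", "extinction_test"))
  expect_error(simulate_cohort(0, 5, 0.5, 0.5, seed = 1), "positive")
  expect_error(simulate_cohort(5, 5, 1.5, 0.5, seed = 1), "\\[0, 1\\]")
})

test_that("phenotype parameter invariants are enforced", {
  expect_error(phenotype_params("x_darter", dart_pulse_peak_mean = 20),
               "23.5")
  expect_error(phenotype_params("x_darter", dart_pulse_width = 0.9), "0.8")
  expect_error(phenotype_params("x_darter", baseline_dart_rate = -1), ">= 0")
  expect_error(
    phenotype_params("x_darter",
                     cs_dart_rate_by_trial = c(rep(0, 5), 6, 5, 4, 3, 2, 1, 0)),
    "non-decreasing"
  )
  # the same decreasing profile is fine for a non-darter
  expect_s3_class(
    phenotype_params("x_nondarter",
                     cs_dart_rate_by_trial = c(rep(0, 5), 6, 5, 4, 3, 2, 1, 0)),
    "phenotype_params"
  )
})
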