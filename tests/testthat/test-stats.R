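test_that("chi-square reproduces the sex-by-Darter association", {
  fit <- chi_square_independence(matrix(c(24, 6, 34, 50), 2))
  expect_equal(fit$statistic, 13.8, tolerance = 0.05 / 13.8)
  expect_equal(fit$p_value, 2e-4, tolerance = 0.05)
  expect_equal(fit$df, 1)
})

test_that("chi-square handles exact independence and hand-computed tables", {
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag <- chi_square_independence(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag$statistic, 10)
  expect_equal(diag$df, 1)

  expect_error(chi_square_independence(matrix(c(1, 1, 0, 0), 2,
                                              byrow = FALSE)),
               "Degenerate")
  expect_error(chi_square_independence(matrix(1:3, 3, 1)), "r x c")
})

test_that("chi-square matches the 2x2 closed form on random tables", {
  set.seed(40)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_independence(tab)$statistic, closed)
  }
})

test_that("Mann-Whitney U handles the pinned orientations and ties", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)  # n_a * n_b / 2

  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 0)     # min of the two orientations
  expect_equal(sep$extra$u_b, 4)
  expect_equal(sep$p_value, 2 * 1 / choose(4, 2))  # exact enumeration

  tied <- mann_whitney_u(5, 5)
  expect_equal(tied$statistic, 0.5)  # midranks

  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the reference rank-sum implementation", {
  set.seed(41)
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:25, 1))
    ours <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(ours$extra$u_a, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-sample branch against the reference normal approximation
  a <- rnorm(30); b <- rnorm(25)
  ours <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("exact and normal-approximation branches agree for moderate n", {
  set.seed(42)
  for (rep in 1:10) {
    a <- rnorm(8)
    b <- rnorm(14)
    exact <- mann_whitney_u(a, b)
    expect_identical(exact$extra$branch, "exact")
    n1 <- 8; n2 <- 14
    z <- (exact$extra$u_a - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    approx_p <- 2 * pnorm(-abs(z))
    expect_lt(abs(exact$p_value - approx_p), 0.05)
  }
})

test_that("Pearson correlation follows the t reference distribution", {
  x <- 1:10
  exact <- pearson_r(x, 2 * x + 1)
  expect_equal(exact$statistic, 1)

  set.seed(43)
  x <- rnorm(2000); y <- rnorm(2000)
  null_fit <- pearson_r(x, y)
  expect_lt(abs(null_fit$statistic), 3 / sqrt(2000))

  x <- rnorm(30); y <- x + rnorm(30)
  fit <- pearson_r(x, y)
  t_stat <- fit$statistic * sqrt((30 - 2) / (1 - fit$statistic^2))
  expect_equal(fit$p_value, 2 * pt(-abs(t_stat), 28), tolerance = 1e-12)

  expect_error(pearson_r(1:3, rep(1, 3)), "variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("mixed ANOVA matches the brute-force SS decomposition exactly", {
  df <- toy_mixed_data()
  fit <- mixed_anova(df)
  ss <- brute_force_mixed_ss(df)
  tb <- tidy(fit)
  get_ss <- function(e) tb$ss[tb$effect == e]
  expect_equal(get_ss("group"), ss$group, tolerance = 1e-10)
  expect_equal(get_ss("subject_within_group"), ss$subj_within, tolerance = 1e-10)
  expect_equal(get_ss("trial"), ss$trial, tolerance = 1e-10)
  expect_equal(get_ss("group_x_trial"), ss$inter, tolerance = 1e-10)
  expect_equal(get_ss("trial_x_subject_within_group"), ss$resid,
               tolerance = 1e-10)
  expect_equal(sum(tb$ss), fit$ss_total, tolerance = 1e-9)
  expect_equal(tb$df, c(1, 4, 2, 2, 8))
})

test_that("mixed ANOVA agrees with the aov error-stratum reference", {
  set.seed(44)
  df <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12), trial = 1:4)
  df$group <- rep(c("a", "b"), each = 24)
  df$value <- rnorm(48) + (df$group == "b") * 0.5 + df$trial * 0.2
  fit <- tidy(mixed_anova(df))
  ref <- summary(aov(value ~ group * factor(trial) +
                       Error(factor(subject)), data = df))
  between <- ref[["Error: factor(subject)"]][[1]]
  within <- ref[["Error: Within"]][[1]]
  expect_equal(fit$statistic[fit$effect == "group"], between[["F value"]][1],
               tolerance = 1e-10)
  expect_equal(fit$statistic[fit$effect == "trial"], within[["F value"]][1],
               tolerance = 1e-10)
  expect_equal(fit$statistic[fit$effect == "group_x_trial"],
               within[["F value"]][2], tolerance = 1e-10)
  expect_equal(fit$p_value[fit$effect == "group"], between[["Pr(>F)"]][1],
               tolerance = 1e-10)
})

test_that("total SS conservation holds for unbalanced groups", {
  set.seed(45)
  for (rep in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1); t_lev <- sample(2:6, 1)
    df <- tidyr::expand_grid(subject = sprintf("s%02d", seq_len(n1 + n2)),
                             trial = seq_len(t_lev))
    df$group <- rep(c("a", "b"), c(n1, n2))[match(df$subject,
                                                  unique(df$subject))]
    df$value <- rnorm(nrow(df))
    fit <- mixed_anova(df)
    expect_equal(sum(fit$table$ss), fit$ss_total,
                 tolerance = 1e-9 * fit$ss_total)
    ss <- brute_force_mixed_ss(df)
    expect_equal(fit$table$ss[1], ss$group, tolerance = 1e-10)
  }
})

test_that("null group effects give near-zero F; degenerate designs error", {
  # identical per-trial group means with subject scatter: F_group exactly 0
  df <- toy_mixed_data()
  mirror <- df
  mirror$subject <- paste0(mirror$subject, "_m")
  mirror$group <- ifelse(df$group == "a", "b", "a")
  both <- dplyr::bind_rows(df, mirror)
  fit <- tidy(mixed_anova(both))
  expect_lt(fit$statistic[fit$effect == "group"], 1e-10)

  incomplete <- df[-1, ]
  expect_error(mixed_anova(incomplete), "Missing cells")
  solo <- df[df$subject %in% c("s1", "s4", "s5"), ]
  expect_error(mixed_anova(solo), "at least 2 subjects")
})

test_that("Sidak post-hoc comparisons adjust at 1 - (1 - alpha)^(1/m)", {
  df <- toy_mixed_data()
  res <- sidak_posthoc(df)
  expect_equal(res$alpha_adjusted, rep(1 - 0.95^(1 / 3), 3))
  expect_equal(1 - 0.95^(1 / 20), 0.002561379, tolerance = 1e-6)

  # identical groups: nothing significant
  set.seed(46)
  same <- df
  same$value <- rep(c(1, 2, 3), 6) + rnorm(18, 0, 1e-3)
  res_same <- sidak_posthoc(same)
  expect_false(any(res_same$significant_adjusted))

  # a large planted gap on one trial only flags that trial
  gap <- df
  gap$value <- rnorm(18, 0, 0.1) + ifelse(gap$trial == 2 & gap$group == "a",
                                          50, 0)
  res_gap <- sidak_posthoc(gap)
  expect_true(res_gap$significant_adjusted[res_gap$trial == "2"])
  expect_false(any(res_gap$significant_adjusted[res_gap$trial != "2"]))

  three_groups <- df
  three_groups$group[three_groups$subject %in% c("s1", "s4")] <- "c"
  expect_error(sidak_posthoc(three_groups), "exactly 2 groups")
})

test_that("tidy and glance return one-row summaries for test objects", {
  fit <- chi_square_independence(matrix(c(24, 6, 34, 50), 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_identical(glance(fit), td)
  g <- glance(mixed_anova(toy_mixed_data()))
  expect_equal(g$n_subjects, 6)
  expect_true(g$gg_epsilon > 0 && g$gg_epsilon <= 1)
})
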