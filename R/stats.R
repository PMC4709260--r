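new_dart_test <- function(test_name, statistic, df, p_value, effect,
                          df2 = NA_real_, extra = list()) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         df = unname(df), df2 = unname(df2), p_value = unname(p_value),
         effect = effect, extra = extra),
    class = "dart_test"
  )
}

#' @export
print.dart_test <- function(x, ...) {
  dfs <- if (is.na(x$df2)) format(x$df) else paste0(x$df, ", ", x$df2)
  cat(sprintf("%s (%s): statistic = %.4g, df = %s, p = %.4g\n",
              x$test_name, x$effect, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' @method tidy dart_test
#' @export
tidy.dart_test <- function(x, ...) {
  tibble(
    test = x$test_name, effect = x$effect, statistic = x$statistic,
    df = x$df, df2 = x$df2, p_value = x$p_value
  )
}

#' @method glance dart_test
#' @export
glance.dart_test <- function(x, ...) tidy(x)

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c count table with
#' `df = (r-1)(c-1)` and an upper-tail p-value. No continuity correction is
#' applied: on the sex-by-Darter table of the original cohort
#' (`[[24, 34], [6, 50]]`) the uncorrected statistic is 13.8 (p = 2e-4),
#' whereas Yates' correction would give about 12.3.
#'
#' @param table An r x c matrix of non-negative counts with positive margins.
#' @return A `dart_test`.
#' @examples
#' chi_square_independence(matrix(c(24, 6, 34, 50), 2))
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) < 2 || ncol(table) < 2) {
    abort("Need an r x c (r, c >= 2) table of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate margins: every row and column sum must be positive.")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_dart_test(
    "chi_square_independence",
    statistic = fit$statistic, df = fit$parameter, p_value = fit$p.value,
    effect = "independence of rows and columns",
    extra = list(expected = fit$expected)
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The reported statistic is the
#' smaller of the two U orientations (so identical samples give
#' `U = n_a * n_b / 2`). The p-value is exact (from the null U distribution)
#' when the smaller sample has at most 8 observations and there are no ties;
#' otherwise a normal approximation with the tie-corrected variance is used.
#' Two-sided.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A `dart_test`; `extra` carries both U orientations and the branch
#'   used.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("Both samples must be non-empty.")
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  u <- min(u_a, u_b)
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (min(n1, n2) <= 8 && !has_ties) {
    p <- if (u_a > n1 * n2 / 2) {
      2 * (1 - pwilcox(u_a - 1, n1, n2))
    } else {
      2 * pwilcox(u_a, n1, n2)
    }
    branch <- "exact"
  } else {
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u_a - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    branch <- "normal_approx"
  }
  new_dart_test(
    "mann_whitney_u", statistic = u, df = NA_real_, p_value = min(1, p),
    effect = "stochastic equality of the two samples",
    extra = list(u_a = u_a, u_b = u_b, branch = branch)
  )
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the usual two-sided t test,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `dart_test` whose statistic is `r`; `extra` carries the t value.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in x or y.")
  fit <- stats::cor.test(x, y, method = "pearson")
  new_dart_test(
    "pearson_r", statistic = unname(fit$estimate), df = fit$parameter,
    p_value = fit$p.value, effect = "linear association",
    extra = list(t = unname(fit$statistic),
                 conf_int = as.numeric(fit$conf.int))
  )
}

#' Two-way mixed-design (split-plot) ANOVA
#'
#' Classical mixed-design decomposition for one between-subject factor
#' (group) crossed with one within-subject factor (trial), complete data:
#' the between-subject sum of squares splits into group and
#' subject-within-group (the error term for group); the within-subject sum
#' of squares splits into trial, group x trial, and trial x
#' subject-within-group (the error term for both within effects). The
#' decomposition is exactly orthogonal (components sum to the total sum of
#' squares), using observation-weighted means, which coincides with the
#' conventional Type III analysis for balanced groups. A Greenhouse-Geisser
#' epsilon is computed from the pooled within-group covariance of the
#' repeated measures and reported, but the uncorrected df are used for the
#' p-values.
#'
#' @param data Long-format data frame with one row per subject-trial.
#' @param value,group,trial,subject Column names (strings or bare names) of
#'   the response, the between-subject factor, the within-subject factor and
#'   the subject id.
#' @return A `mixed_anova` object. [tidy()] returns the full ANOVA table
#'   (one row per effect, including error strata); [glance()] a one-row
#'   summary with the Greenhouse-Geisser epsilon.
#' @examples
#' df <- tidyr::expand_grid(subject = 1:6, trial = 1:3)
#' df$group <- rep(c("a", "b"), each = 9)
#' df$value <- rnorm(18)
#' tidy(mixed_anova(df))
#' @export
mixed_anova <- function(data, value = "value", group = "group",
                        trial = "trial", subject = "subject") {
  value <- as_col_name(rlang::enquo(value), data)
  group <- as_col_name(rlang::enquo(group), data)
  trial <- as_col_name(rlang::enquo(trial), data)
  subject <- as_col_name(rlang::enquo(subject), data)

  d <- tibble(
    y = as.numeric(data[[value]]),
    g = as.character(data[[group]]),
    tr = as.character(data[[trial]]),
    s = as.character(data[[subject]])
  )
  if (anyNA(d$y)) abort("Missing cells: every subject needs a value for every trial.")
  tab <- table(d$s, d$tr)
  if (any(tab != 1)) {
    abort("Missing cells: every subject needs exactly one value per trial.")
  }
  groups <- sort(unique(d$g))
  trials <- sort(unique(d$tr))
  g <- length(groups)
  t_lev <- length(trials)
  if (g < 2 || t_lev < 2) abort("Need at least 2 groups and 2 trials.")

  subj_group <- dplyr::distinct(d[, c("s", "g")])
  if (nrow(subj_group) != length(unique(d$s))) {
    abort("Each subject must belong to exactly one group.")
  }
  n_j <- table(factor(subj_group$g, levels = groups))
  if (any(n_j < 2)) abort("Every group needs at least 2 subjects.")
  n_subj <- sum(n_j)

  grand <- mean(d$y)
  subj_means <- tapply(d$y, d$s, mean)
  group_means <- tapply(d$y, factor(d$g, levels = groups), mean)
  trial_means <- tapply(d$y, factor(d$tr, levels = trials), mean)
  cell_means <- tapply(d$y, list(factor(d$g, levels = groups),
                                 factor(d$tr, levels = trials)), mean)

  ss_total <- sum((d$y - grand)^2)
  ss_between_subj <- t_lev * sum((subj_means - grand)^2)
  ss_group <- t_lev * sum(n_j * (group_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_trial <- n_subj * sum((trial_means - grand)^2)
  inter_dev <- sweep(sweep(cell_means, 1, group_means), 2, trial_means) + grand
  ss_inter <- sum(as.numeric(n_j) * inter_dev^2)
  ss_resid <- ss_total - ss_between_subj - ss_trial - ss_inter

  df_group <- g - 1
  df_subj <- n_subj - g
  df_trial <- t_lev - 1
  df_inter <- (g - 1) * (t_lev - 1)
  df_resid <- (n_subj - g) * (t_lev - 1)

  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  f_trial <- ms(ss_trial, df_trial) / ms(ss_resid, df_resid)
  f_inter <- ms(ss_inter, df_inter) / ms(ss_resid, df_resid)

  tbl <- tibble(
    effect = c("group", "subject_within_group", "trial", "group_x_trial",
               "trial_x_subject_within_group"),
    ss = c(ss_group, ss_subj_within, ss_trial, ss_inter, ss_resid),
    df = c(df_group, df_subj, df_trial, df_inter, df_resid),
    ms = .data$ss / .data$df,
    statistic = c(f_group, NA, f_trial, f_inter, NA),
    df_error = c(df_subj, NA, df_resid, df_resid, NA),
    p_value = c(
      pf(f_group, df_group, df_subj, lower.tail = FALSE), NA,
      pf(f_trial, df_trial, df_resid, lower.tail = FALSE),
      pf(f_inter, df_inter, df_resid, lower.tail = FALSE), NA
    )
  )

  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the repeated measures, via orthonormal contrasts
  wide <- matrix(NA_real_, n_subj, t_lev)
  subj_ids <- subj_group$s
  for (i in seq_len(n_subj)) {
    rows <- d[d$s == subj_ids[i], ]
    wide[i, ] <- rows$y[match(trials, rows$tr)]
  }
  pooled <- matrix(0, t_lev, t_lev)
  for (j in seq_along(groups)) {
    rows <- wide[subj_group$g == groups[j], , drop = FALSE]
    if (nrow(rows) > 1) pooled <- pooled + stats::cov(rows) * (nrow(rows) - 1)
  }
  pooled <- pooled / (n_subj - g)
  contrasts <- qr.Q(qr(stats::contr.helmert(t_lev)))
  m <- t(contrasts) %*% pooled %*% contrasts
  gg_epsilon <- (sum(diag(m))^2) / ((t_lev - 1) * sum(m^2))

  structure(
    list(
      table = tbl, ss_total = ss_total, gg_epsilon = unname(gg_epsilon),
      n_subjects = n_subj, n_groups = g, n_trials = t_lev,
      group_sizes = as.integer(n_j), groups = groups, trials = trials,
      cell_means = cell_means,
      ms_resid = ms(ss_resid, df_resid), df_resid = df_resid
    ),
    class = "mixed_anova"
  )
}

as_col_name <- function(quo, data) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (is.character(expr)) expr else rlang::as_name(quo)
  if (!nm %in% names(data)) abort(sprintf("Column '%s' not found.", nm))
  nm
}

#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) x$table

#' @method glance mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects, n_groups = x$n_groups, n_trials = x$n_trials,
    ss_total = x$ss_total, gg_epsilon = x$gg_epsilon
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA: %d subjects (%s), %d trials\n",
              x$n_subjects, paste(x$group_sizes, collapse = "/"), x$n_trials))
  print(x$table)
  cat(sprintf("Greenhouse-Geisser epsilon = %.3f (not applied)\n", x$gg_epsilon))
  invisible(x)
}

#' Sidak-adjusted per-trial group comparisons
#'
#' Follows up a two-group mixed-design ANOVA with one comparison per trial,
#' using the within-subject error term (trial x subject-within-group mean
#' square) as the denominator. With `m` trials the Sidak-adjusted per-test
#' level is `1 - (1 - alpha)^(1/m)` (about 0.00256 for 20 trials at
#' alpha = 0.05); adjusted p-values are `1 - (1 - p)^m`. Both raw and
#' adjusted decisions are reported.
#'
#' @inheritParams mixed_anova
#' @param alpha Familywise level (default 0.05).
#' @return A tibble with one row per trial: group means, difference,
#'   standard error, t statistic, raw and adjusted p-values and decisions.
#' @export
sidak_posthoc <- function(data, value = "value", group = "group",
                          trial = "trial", subject = "subject",
                          alpha = 0.05) {
  fit <- mixed_anova(data, {{ value }}, {{ group }}, {{ trial }}, {{ subject }})
  if (fit$n_groups != 2) {
    abort("Sidak post-hoc comparisons require exactly 2 groups.")
  }
  m <- fit$n_trials
  alpha_adj <- 1 - (1 - alpha)^(1 / m)
  n1 <- fit$group_sizes[1]
  n2 <- fit$group_sizes[2]
  se <- sqrt(fit$ms_resid * (1 / n1 + 1 / n2))
  diff <- fit$cell_means[1, ] - fit$cell_means[2, ]
  tstat <- diff / se
  p_raw <- 2 * pt(-abs(tstat), fit$df_resid)
  tibble(
    trial = fit$trials,
    mean_1 = fit$cell_means[1, ],
    mean_2 = fit$cell_means[2, ],
    estimate = unname(diff),
    se = se,
    statistic = unname(tstat),
    df = fit$df_resid,
    p_value = unname(p_raw),
    p_adjusted = pmin(1, 1 - (1 - unname(p_raw))^m),
    alpha_adjusted = alpha_adj,
    significant_raw = unname(p_raw) < alpha,
    significant_adjusted = unname(p_raw) < alpha_adj
  )
}
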