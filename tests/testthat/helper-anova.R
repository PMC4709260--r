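# independent brute-force mixed-design SS decomposition: explicit loops over
# the textbook definitions, no shared code with the implementation
brute_force_mixed_ss <- function(df) {
  subjects <- unique(df$subject)
  trials <- sort(unique(df$trial))
  grand <- mean(df$value)
  ss <- list(total = 0, between_subj = 0, group = 0, trial = 0, inter = 0)
  for (i in seq_len(nrow(df))) ss$total <- ss$total + (df$value[i] - grand)^2
  for (s in subjects) {
    m_s <- mean(df$value[df$subject == s])
    ss$between_subj <- ss$between_subj + length(trials) * (m_s - grand)^2
  }
  for (g in unique(df$group)) {
    rows <- df$group == g
    n_g <- length(unique(df$subject[rows]))
    ss$group <- ss$group + length(trials) * n_g *
      (mean(df$value[rows]) - grand)^2
  }
  for (tr in trials) {
    ss$trial <- ss$trial + length(subjects) *
      (mean(df$value[df$trial == tr]) - grand)^2
  }
  for (g in unique(df$group)) {
    n_g <- length(unique(df$subject[df$group == g]))
    for (tr in trials) {
      cell <- mean(df$value[df$group == g & df$trial == tr])
      dev <- cell - mean(df$value[df$group == g]) -
        mean(df$value[df$trial == tr]) + grand
      ss$inter <- ss$inter + n_g * dev^2
    }
  }
  ss$subj_within <- ss$between_subj - ss$group
  ss$resid <- ss$total - ss$between_subj - ss$trial - ss$inter
  ss
}

toy_mixed_data <- function() {
  # 2 groups x 3 trials, 3 subjects per group
  vals <- c(
    3, 4, 7,   2, 4, 6,   5, 6, 9,    # group a subjects
    1, 2, 2,   2, 3, 5,   0, 1, 3     # group b subjects
  )
  tibble::tibble(
    subject = rep(sprintf("s%d", 1:6), each = 3),
    group = rep(c("a", "b"), each = 9),
    trial = rep(1:3, 6),
    value = vals
  )
}
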