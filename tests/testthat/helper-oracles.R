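# Hand-derived first generations, frozen as independent oracles for the
# rewriting engine (0 -> 1, 1 -> 01 applied symbol by symbol).
FIB_GENERATIONS <- c("0", "1", "01", "101", "01101", "10101101")
SKIP_GENERATIONS <- c("0", "01", "0101101")

# Fibonacci numbers by plain recurrence, independent of the package.
fib_lengths <- function(n) {
  lens <- c(1, 1)
  for (i in 3:(n + 1)) lens[i] <- lens[i - 1] + lens[i - 2]
  lens
}

# Brute-force within-subject two-way decomposition from first principles:
# explicit mean-deviation sums, no model fitting. Used as the independent
# oracle against rm_anova_two_way().
brute_force_rm_anova <- function(df) {
  S <- factor(df$subject); A <- factor(df$a); B <- factor(df$b)
  y <- df$y
  s <- nlevels(S); a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  m_s <- tapply(y, S, mean); m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_sa <- tapply(y, list(S, A), mean)
  m_sb <- tapply(y, list(S, B), mean)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_a <- s * b * sum((m_a - grand)^2)
  ss_b <- s * a * sum((m_b - grand)^2)
  ss_ab <- 0
  for (i in levels(A)) for (j in levels(B)) {
    ss_ab <- ss_ab + s * (m_ab[i, j] - m_a[i] - m_b[j] + grand)^2
  }
  ss_sa <- 0
  for (k in levels(S)) for (i in levels(A)) {
    ss_sa <- ss_sa + b * (m_sa[k, i] - m_s[k] - m_a[i] + grand)^2
  }
  ss_sb <- 0
  for (k in levels(S)) for (j in levels(B)) {
    ss_sb <- ss_sb + a * (m_sb[k, j] - m_s[k] - m_b[j] + grand)^2
  }
  ss_total <- sum((y - grand)^2)
  ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  out <- list(ss_s = ss_s, ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
              ss_sa = ss_sa, ss_sb = ss_sb, ss_sab = ss_sab,
              ss_total = ss_total,
              f_a = (ss_a / (a - 1)) / (ss_sa / ((a - 1) * (s - 1))),
              f_b = (ss_b / (b - 1)) / (ss_sb / ((b - 1) * (s - 1))),
              f_ab = (ss_ab / ((a - 1) * (b - 1))) /
                (ss_sab / ((a - 1) * (b - 1) * (s - 1))))
  lapply(out, function(v) unname(as.numeric(v)))
}

# Random complete balanced within-subject design.
random_balanced_design <- function(n_subjects, levels_a, levels_b) {
  df <- expand.grid(subject = seq_len(n_subjects),
                    a = paste0("a", seq_len(levels_a)),
                    b = paste0("b", seq_len(levels_b)))
  df$y <- stats::rnorm(nrow(df), 500, 60) +
    rep(stats::rnorm(n_subjects, 0, 40), times = levels_a * levels_b)
  df
}

# Analysis-3 Grammar p-value for one simulated cohort.
analysis3_grammar_p <- function(cohort) {
  res <- suppressWarnings(run_analysis(cohort, 3))
  res$anova$effects$p[res$anova$effects$effect == "grammar"]
}
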