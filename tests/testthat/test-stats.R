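trials <- build_trials()

make_flat_cohort <- function(rt_value = 500) {
  co <- simulate_cohort(3, learner_spec("static"),
                        rt_params(subject_sd = 0, noise_sd = 0),
                        master_seed = 1, trials = trials)
  co$rt_ms <- rt_value
  co$timeout <- FALSE
  co$correct <- TRUE
  co
}

test_that("condition means recover a constant cohort exactly", {
  cells <- condition_means(make_flat_cohort(500), "a1", "block")
  expect_true(all(cells$mean_rt == 500))
  expect_true(all(cells$accuracy == 1))
  expect_identical(nrow(cells), 3L * 2L * 4L)
})

test_that("condition means match hand-computed averages on a tiny fixture", {
  co <- make_flat_cohort()
  # subject 1, congruent a1 targets in block 1: plant known RTs
  rows <- which(co$subject == 1 & co$a1_target & co$block == 1 &
                  co$congruency == "congruent")
  co$rt_ms[rows] <- 400
  co$rt_ms[rows[1:2]] <- c(600, 800)
  co$correct[rows[3]] <- FALSE  # error trials leave the RT mean
  n_ok <- length(rows) - 1L
  expected <- (600 + 800 + 400 * (n_ok - 2)) / n_ok
  cells <- condition_means(co, "a1", "block")
  got <- cells[cells$subject == 1 & cells$congruency == "congruent" &
                 cells$block == 1, ]
  expect_equal(got$mean_rt, expected)
  expect_equal(got$accuracy, (length(rows) - 1) / length(rows))
  expect_identical(got$n_trials, n_ok)
})

test_that("empty cells either error with the cell named or drop the subject", {
  co <- make_flat_cohort()
  kill <- co$subject == 2 & co$a3_target & co$grammar == "skip" &
    co$congruency == "incongruent"
  co$correct[kill] <- FALSE
  err <- expect_error(condition_means(co, "a3", "grammar"),
                      class = "agl_empty_cell_error")
  expect_match(conditionMessage(err), "subject 2")
  expect_warning(cells <- condition_means(co, "a3", "grammar",
                                          on_empty = "drop"),
                 class = "agl_empty_cell_warning")
  expect_false(2 %in% cells$subject)
  expect_identical(attr(cells, "dropped_subjects"), 2L)
})

test_that("a constant design yields zero F and zero partial eta squared", {
  cells <- expand.grid(subject = 1:4, congruency = c("c", "i"), block = 1:4)
  cells$mean_rt <- 500
  res <- rm_anova_two_way(cells, factor_b = "block")
  expect_true(all(res$effects$f == 0))
  expect_true(all(res$effects$p == 1))
  expect_true(all(res$effects$partial_eta_sq == 0))
})

test_that("the ANOVA matches a first-principles decomposition on a fixture", {
  set.seed(99)
  df <- random_balanced_design(3, 2, 2)
  oracle <- brute_force_rm_anova(df)
  res <- rm_anova_two_way(df, dv = "y", factor_a = "a", factor_b = "b")
  eff <- res$effects
  expect_equal(eff$ss[1], oracle$ss_a, tolerance = 1e-9)
  expect_equal(eff$ss[2], oracle$ss_b, tolerance = 1e-9)
  expect_equal(eff$ss[3], oracle$ss_ab, tolerance = 1e-9)
  expect_equal(eff$ss_error, c(oracle$ss_sa, oracle$ss_sb, oracle$ss_sab),
               tolerance = 1e-9)
  expect_equal(eff$f, c(oracle$f_a, oracle$f_b, oracle$f_ab),
               tolerance = 1e-9)
  expect_equal(eff$partial_eta_sq[1],
               oracle$ss_a / (oracle$ss_a + oracle$ss_sa), tolerance = 1e-9)
})

test_that("ANOVA agrees with the brute-force oracle on 50 random designs", {
  set.seed(2024)
  for (i in 1:50) {
    df <- random_balanced_design(sample(3:8, 1), sample(2:4, 1),
                                 sample(2:4, 1))
    oracle <- brute_force_rm_anova(df)
    res <- rm_anova_two_way(df, dv = "y", factor_a = "a", factor_b = "b")
    eff <- res$effects
    expect_equal(eff$ss, c(oracle$ss_a, oracle$ss_b, oracle$ss_ab),
                 tolerance = 1e-9)
    expect_equal(eff$f, c(oracle$f_a, oracle$f_b, oracle$f_ab),
                 tolerance = 1e-9)
    # conservation: all seven components reassemble the total variation
    parts <- oracle$ss_s + oracle$ss_a + oracle$ss_b + oracle$ss_ab +
      oracle$ss_sa + oracle$ss_sb + oracle$ss_sab
    expect_equal(parts, oracle$ss_total, tolerance = 1e-9)
    expect_equal(res$summary$ss_total, oracle$ss_total, tolerance = 1e-9)
    # dfs follow the balanced within-subject layout
    s <- length(unique(df$subject))
    a <- length(unique(df$a)); b <- length(unique(df$b))
    expect_identical(eff$df, c(a - 1, b - 1, (a - 1) * (b - 1)))
    expect_identical(eff$df_error,
                     c((a - 1) * (s - 1), (b - 1) * (s - 1),
                       (a - 1) * (b - 1) * (s - 1)))
  }
})

test_that("incomplete designs are rejected with the missing cells named", {
  df <- random_balanced_design(3, 2, 2)
  err <- expect_error(
    rm_anova_two_way(df[-1, ], dv = "y", factor_a = "a", factor_b = "b"),
    class = "agl_incomplete_design_error")
  expect_match(conditionMessage(err), "subject")
  one <- random_balanced_design(1, 2, 2)
  expect_error(rm_anova_two_way(one, dv = "y", factor_a = "a",
                                factor_b = "b"),
               class = "agl_incomplete_design_error")
})

test_that("Bonferroni pairwise comparisons follow the paired t closed form", {
  df <- expand.grid(subject = 1:3, block = paste0("b", 1:4))
  df$mean_rt <- c(500, 520, 480, 510, 525, 470, 490, 505, 460, 505, 515, 475)
  pw <- bonferroni_pairwise(df)
  expect_identical(nrow(pw), 6L)  # 4 levels -> 6 comparisons
  # closed-form paired t for one pair, coded independently
  wide <- tapply(df$mean_rt, list(df$subject, df$block), mean)
  d <- wide[, "b1"] - wide[, "b2"]
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(abs(t_manual), df = 2, lower.tail = FALSE)
  row <- pw[pw$level_1 == "b1" & pw$level_2 == "b2", ]
  expect_equal(row$t, t_manual, tolerance = 1e-12)
  expect_equal(row$p_raw, p_manual, tolerance = 1e-12)
  expect_equal(row$p_bonferroni, min(1, 6 * p_manual), tolerance = 1e-12)
  expect_true(all(pw$p_bonferroni >= pw$p_raw - 1e-15))
})

test_that("identical levels give t = 0 and a capped p-value", {
  df <- expand.grid(subject = 1:4, block = c("b1", "b2"))
  df$mean_rt <- rep(c(480, 500, 520, 490), 2)
  pw <- bonferroni_pairwise(df)
  expect_identical(pw$t, 0)
  expect_identical(pw$p_bonferroni, 1)
  # constant non-zero difference: degenerate variance
  df$mean_rt[df$block == "b2"] <- df$mean_rt[df$block == "b2"] + 10
  expect_warning(pw2 <- bonferroni_pairwise(df),
                 class = "agl_degenerate_variance_warning")
  expect_identical(pw2$mean_diff, -10)
  expect_true(is.na(pw2$t))
})

test_that("analysis bundles have the published table shapes", {
  co <- simulate_cohort(6, master_seed = 42, trials = trials)
  a1 <- suppressWarnings(run_analysis(co, 1))
  expect_identical(nrow(a1$rt_table), 8L)        # 2 congruency x 4 blocks
  expect_identical(nrow(a1$accuracy_table), 8L)
  expect_identical(nrow(a1$pairwise), 6L)
  expect_identical(a1$factor_b, "block")
  a3 <- suppressWarnings(run_analysis(co, 3))
  expect_identical(nrow(a3$rt_table), 4L)        # 2 congruency x 2 grammars
  expect_null(a3$pairwise)
  expect_identical(levels(a3$cells$grammar), c("fib", "skip"))
  expect_error(run_analysis(co, 4), class = "agl_argument_error")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(a3, path)
  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$analysis, 3L)
  expect_identical(length(parsed$anova$effects), 3L)
})

test_that("static cohorts show no spurious Block effect in Analysis 1", {
  p_block <- vapply(1:100, function(r) {
    co <- simulate_cohort(22, learner_spec("static"), rt_params(),
                          master_seed = 300 + r, trials = trials)
    res <- suppressWarnings(run_analysis(co, 1))
    res$anova$effects$p[res$anova$effects$effect == "block"]
  }, numeric(1))
  expect_gte(sum(p_block >= 0.05), 90)
})

test_that("shuffling grammar labels within subject destroys the effect", {
  co <- simulate_cohort(22, master_seed = 77, trials = trials)
  set.seed(123)
  p_perm <- vapply(1:100, function(i) {
    shuffled <- co
    for (s in unique(co$subject)) {
      rows <- which(co$subject == s & co$a3_target)
      shuffled$grammar[rows] <- sample(co$grammar[rows])
    }
    analysis3_grammar_p(shuffled)
  }, numeric(1))
  expect_gt(median(p_perm), 0.2)
})
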