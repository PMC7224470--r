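#' Per-subject condition means on correct trials
#'
#' Builds the cell means the repeated-measures analyses consume: one row per
#' subject x congruency x second-factor level, restricted to the trials
#' flagged for the chosen analysis context. Mean RT is computed over
#' correct, non-timeout trials only; accuracy is the proportion correct over
#' all target trials in the cell (timeouts count as errors).
#'
#' @param cohort A cohort from [simulate_cohort()] or [read_cohort()].
#' @param target_flag Which analysis context to keep: `"a1"` (blue after
#'   red), `"a2"` (red after two blues) or `"a3"` (blue after red-blue).
#' @param factor_b Second within-subject factor: `"block"` (four levels) or
#'   `"grammar"` (two levels, blocks 1-3 pooled as `fib`).
#' @param on_empty What to do when a subject has a cell with no correct
#'   trials: `"error"` (default; names the subject and cell) or `"drop"`
#'   (listwise-delete the subject with a warning).
#' @return A [tibble][tibble::tibble] with columns `subject`, `congruency`,
#'   the factor column, `mean_rt`, `accuracy`, `n_trials` (trials
#'   contributing to the RT mean).
#' @export
condition_means <- function(cohort,
                            target_flag = c("a1", "a2", "a3"),
                            factor_b = c("block", "grammar"),
                            on_empty = c("error", "drop")) {
  target_flag <- match.arg(target_flag)
  factor_b <- match.arg(factor_b)
  on_empty <- match.arg(on_empty)
  flag_col <- paste0(target_flag, "_target")
  data <- cohort[cohort[[flag_col]], , drop = FALSE]
  if (factor_b == "grammar") {
    data$grammar <- factor(data$grammar, levels = c("fib", "skip"))
  } else {
    data$block <- factor(data$block, levels = sort(unique(cohort$block)))
  }
  cells <- dplyr::summarise(
    dplyr::group_by(data, .data$subject, .data$congruency,
                    .data[[factor_b]], .drop = FALSE),
    mean_rt = mean(.data$rt_ms[.data$correct & !.data$timeout]),
    accuracy = mean(.data$correct),
    n_trials = sum(.data$correct & !.data$timeout),
    .groups = "drop")
  empty <- cells[cells$n_trials == 0, , drop = FALSE]
  if (nrow(empty) > 0) {
    desc <- paste(sprintf("subject %s (%s, %s = %s)", empty$subject,
                          empty$congruency, factor_b, empty[[factor_b]]),
                  collapse = "; ")
    if (on_empty == "error") {
      agl_error(paste0("empty cells (no correct trials): ", desc),
                "agl_empty_cell_error")
    }
    agl_warn(paste0("dropping subjects with empty cells: ", desc),
             "agl_empty_cell_warning")
    cells <- cells[!(cells$subject %in% empty$subject), , drop = FALSE]
  }
  attr(cells, "factor_b") <- factor_b
  attr(cells, "dropped_subjects") <- unique(empty$subject)
  cells
}

#' Two-factor within-subject (repeated-measures) ANOVA
#'
#' Classical fully-within decomposition for a complete balanced design:
#' total variation splits into subjects, the two main effects, their
#' interaction, and the three effect-by-subject error strata; each effect is
#' tested against its own error term (F_A = MS_A / MS_AxS and so on). The
#' decomposition is fitted with [stats::aov()] using an
#' `Error(subject/(A*B))` stratification; F, p and partial eta squared
#' (SS_effect / (SS_effect + SS_error)) are derived from the extracted sums
#' of squares. Effects with zero sum of squares are reported as F = 0, p =
#' 1, partial eta squared = 0.
#'
#' @param cells A condition-mean table from [condition_means()] (or any data
#'   frame with one observation per subject x cell).
#' @param dv Name of the response column.
#' @param subject,factor_a Column names of the subject identifier and first
#'   factor.
#' @param factor_b Column name of the second factor; by default taken from
#'   the `condition_means()` attribute.
#' @return An object of class `anova_rm`: a list with `effects` (tibble: one
#'   row per effect with SS, df, MS, F, p, partial eta squared and the
#'   matching error SS/df/MS) and `summary` (subjects, levels, SS_subjects,
#'   SS_total).
#' @export
rm_anova_two_way <- function(cells, dv = "mean_rt", subject = "subject",
                             factor_a = "congruency",
                             factor_b = attr(cells, "factor_b")) {
  if (is.null(factor_b)) {
    agl_error("factor_b must be supplied when cells carry no attribute",
              "agl_argument_error")
  }
  df <- data.frame(y = cells[[dv]],
                   S = factor(cells[[subject]]),
                   A = factor(cells[[factor_a]]),
                   B = factor(cells[[factor_b]]))
  if (anyNA(df$y)) {
    agl_error("response contains NA; drop or fill empty cells first",
              "agl_incomplete_design_error")
  }
  counts <- table(df$S, df$A, df$B)
  if (any(counts != 1)) {
    bad <- which(counts == 0, arr.ind = TRUE)
    msg <- if (nrow(bad) > 0) {
      paste(sprintf("subject %s: %s x %s", dimnames(counts)[[1]][bad[, 1]],
                    dimnames(counts)[[2]][bad[, 2]],
                    dimnames(counts)[[3]][bad[, 3]]), collapse = "; ")
    } else "duplicated cells"
    agl_error(paste0("design is not complete and balanced: ", msg),
              "agl_incomplete_design_error")
  }
  s <- nlevels(df$S)
  if (s < 2) {
    agl_error("need at least 2 subjects", "agl_incomplete_design_error")
  }

  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = df)
  strata <- summary(fit)
  ss <- function(stratum, row) {
    tab <- strata[[stratum]][[1]]
    idx <- match(row, trimws(rownames(tab)))
    c(ss = tab[idx, "Sum Sq"], df = tab[idx, "Df"])
  }
  effects <- c("A", "B", "A:B")
  err_strata <- c("Error: S:A", "Error: S:B", "Error: S:A:B")
  rows <- lapply(seq_along(effects), function(i) {
    e <- ss(err_strata[i], effects[i])
    r <- ss(err_strata[i], "Residuals")
    ms <- e[["ss"]] / e[["df"]]
    ms_err <- r[["ss"]] / r[["df"]]
    if (e[["ss"]] <= .Machine$double.eps^0.75) {
      f <- 0; p <- 1; pes <- 0
    } else {
      f <- ms / ms_err
      p <- stats::pf(f, e[["df"]], r[["df"]], lower.tail = FALSE)
      pes <- e[["ss"]] / (e[["ss"]] + r[["ss"]])
    }
    tibble::tibble(effect = c(factor_a, factor_b,
                              paste0(factor_a, ":", factor_b))[i],
                   ss = e[["ss"]], df = e[["df"]], ms = ms,
                   f = f, p = p, partial_eta_sq = pes,
                   ss_error = r[["ss"]], df_error = r[["df"]],
                   ms_error = ms_err)
  })
  subj_tab <- strata[["Error: S"]][[1]]
  out <- structure(
    list(effects = dplyr::bind_rows(rows),
         summary = list(n_subjects = s,
                        levels_a = levels(df$A), levels_b = levels(df$B),
                        ss_subjects = subj_tab[1, "Sum Sq"],
                        ss_total = sum(vapply(
                          strata, function(x) sum(x[[1]][, "Sum Sq"]),
                          numeric(1))))),
    class = "anova_rm")
  out
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("Within-subject ANOVA: %d subjects, %s (%d) x %s (%d)\n",
              x$summary$n_subjects, x$effects$effect[1],
              length(x$summary$levels_a), x$effects$effect[2],
              length(x$summary$levels_b)))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-22s F(%d, %d) = %7.3f, p = %.4g, partial eta sq = %.3f\n",
                eff$effect[i], eff$df[i], eff$df_error[i], eff$f[i],
                eff$p[i], eff$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t-tests between all level pairs of a within-subject factor, on the
#' per-subject marginal means; p-values are multiplied by the number of
#' pairs m = L(L-1)/2 and capped at 1. When a pair's within-subject
#' differences are all exactly zero the comparison is reported as t = 0,
#' p = 1; a pair with zero variance around a non-zero difference is reported
#' with the mean difference and an undefined t (degenerate variance).
#'
#' @param data Data frame with one observation per subject x level (e.g.
#'   marginal means over congruency).
#' @param value,subject,level Column names.
#' @return A [tibble][tibble::tibble] with one row per level pair:
#'   `level_1`, `level_2`, `mean_diff`, `t`, `df`, `p_raw`, `p_bonferroni`.
#' @export
bonferroni_pairwise <- function(data, value = "mean_rt",
                                subject = "subject", level = "block") {
  lv <- factor(data[[level]])
  if (nlevels(lv) < 2) {
    agl_error("need at least 2 levels for pairwise comparisons",
              "agl_argument_error")
  }
  wide <- tapply(data[[value]], list(factor(data[[subject]]), lv), mean)
  if (anyNA(wide)) {
    agl_error("every subject needs a value at every level",
              "agl_incomplete_design_error")
  }
  pairs <- utils::combn(levels(lv), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    d <- wide[, pairs[1, j]] - wide[, pairs[2, j]]
    n <- length(d)
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        t_stat <- 0; p_raw <- 1
      } else {
        agl_warn(sprintf("degenerate variance for pair %s vs %s",
                         pairs[1, j], pairs[2, j]),
                 "agl_degenerate_variance_warning")
        t_stat <- NA_real_; p_raw <- NA_real_
      }
    } else {
      tt <- stats::t.test(d)
      t_stat <- unname(tt$statistic)
      p_raw <- tt$p.value
    }
    tibble::tibble(level_1 = pairs[1, j], level_2 = pairs[2, j],
                   mean_diff = mean(d), t = t_stat, df = n - 1L,
                   p_raw = p_raw, p_bonferroni = pmin(1, m * p_raw))
  })
  dplyr::bind_rows(rows)
}

#' Run one of the three study analyses
#'
#' Analysis 1 tests First-Law learning: congruency x block (4 levels) on
#' blue trials following a red. Analysis 2 tests Second-Law learning: the
#' same design on red trials following two blues. Analysis 3 tests
#' sensitivity to hierarchical structure: congruency x grammar (Fibonacci
#' blocks pooled vs Skip) on blue trials following a red-blue pair -- the
#' k-point contexts. RT cell means feed a within-subject ANOVA; block
#' analyses add Bonferroni pairwise comparisons of the block marginal means
#' (congruency pooled at the subject level). Accuracy is reported
#' descriptively only. Subjects with an empty cell are dropped listwise with
#' a warning.
#'
#' @param cohort A cohort dataset.
#' @param which Analysis number: 1, 2 or 3.
#' @return An object of class `agl_analysis`: a list with `analysis`,
#'   `target_flag`, `factor_b`, `cells` (per-subject condition means),
#'   `rt_table` and `accuracy_table` (group mean and SD per cell, the shape
#'   of the published tables), `anova`, `pairwise` (block analyses only) and
#'   `dropped_subjects`.
#'
#' @examples
#' cohort <- simulate_cohort(n_subjects = 6, master_seed = 42)
#' run_analysis(cohort, 1)
#' @export
run_analysis <- function(cohort, which) {
  if (!which %in% 1:3) {
    agl_error("which must be 1, 2 or 3", "agl_argument_error")
  }
  target_flag <- c("a1", "a2", "a3")[which]
  factor_b <- if (which == 3) "grammar" else "block"
  cells <- condition_means(cohort, target_flag, factor_b, on_empty = "drop")
  anova <- rm_anova_two_way(cells)

  summarise_cells <- function(value) {
    agg <- dplyr::summarise(
      dplyr::group_by(cells, .data$congruency, .data[[factor_b]]),
      mean = mean(.data[[value]]), sd = stats::sd(.data[[value]]),
      .groups = "drop")
    agg
  }
  pairwise <- NULL
  if (factor_b == "block") {
    marginal <- dplyr::summarise(
      dplyr::group_by(cells, .data$subject, .data$block),
      mean_rt = mean(.data$mean_rt), .groups = "drop")
    pairwise <- bonferroni_pairwise(marginal, level = "block")
  }
  structure(list(analysis = which, target_flag = target_flag,
                 factor_b = factor_b, cells = cells,
                 rt_table = summarise_cells("mean_rt"),
                 accuracy_table = summarise_cells("accuracy"),
                 anova = anova, pairwise = pairwise,
                 dropped_subjects = attr(cells, "dropped_subjects")),
            class = "agl_analysis")
}

#' @export
print.agl_analysis <- function(x, ...) {
  cat(sprintf("Analysis %d: %s targets, congruency x %s\n", x$analysis,
              x$target_flag, x$factor_b))
  if (length(x$dropped_subjects)) {
    cat("  dropped subjects (empty cells):",
        paste(x$dropped_subjects, collapse = ", "), "\n")
  }
  cat("Mean RT (ms) per cell:\n")
  wide <- tapply(x$rt_table$mean,
                 list(x$rt_table$congruency, x$rt_table[[x$factor_b]]), mean)
  print(round(wide, 2))
  print(x$anova)
  if (!is.null(x$pairwise)) {
    cat("Bonferroni pairwise (block marginals):\n")
    pw <- x$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("  %s vs %s: diff = %7.2f, t(%d) = %6.2f, p_bonf = %.4g\n",
                  pw$level_1[i], pw$level_2[i], pw$mean_diff[i], pw$df[i],
                  pw$t[i], pw$p_bonferroni[i]))
    }
  }
  invisible(x)
}

#' Serialize an analysis bundle to JSON
#'
#' @param analysis An `agl_analysis` from [run_analysis()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path) {
  payload <- list(
    analysis = analysis$analysis,
    target_flag = analysis$target_flag,
    factor_b = analysis$factor_b,
    dropped_subjects = analysis$dropped_subjects,
    rt_table = analysis$rt_table,
    accuracy_table = analysis$accuracy_table,
    anova = list(effects = analysis$anova$effects,
                 n_subjects = analysis$anova$summary$n_subjects),
    pairwise = analysis$pairwise)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
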