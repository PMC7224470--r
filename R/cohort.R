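#' Learner specification
#'
#' Three nested learner models dissociate the study's analyses. The *static*
#' learner never updates: its expectancy is pinned at 0.5 per symbol and both
#' gains are ignored, so its reaction times carry no sequence information.
#' The *sequential* learner keeps one expectancy trace per left context
#' (after-0, after-single-1, after-11, start) and symbol, updated
#' exponentially on every observation: `new = (1 - rate) * old +
#' rate * observed`, starting from 0 ("no expectancy"); after N consecutive
#' confirmations a trace sits at `1 - (1 - rate)^N`. The *structural* learner
#' adds k-point tracking on top: once its after-0 expectancy for a 1 exceeds
#' `first_law_threshold` (the First Law has been acquired), it segments the
#' stream into \[01\] chunks online, notes the stranded 1s, and projects the
#' position of the next one whenever the gap pattern forces it (a 3-gap is
#' always followed by a 5-gap, and a 5,5 pair by a 3-gap). Trials landing on
#' a projected slot receive the extra `k_gain` anticipation benefit. On a
#' Skip stream the forced gap patterns (essentially) never occur, so the
#' tracker stays silent there.
#'
#' @param kind One of `"static"`, `"sequential"`, `"structural"`.
#' @param learning_rate Per-observation exponential update weight in (0, 1].
#' @param anticipation_gain Maximal RT benefit (ms) for a fully expected
#'   symbol; scales with the expectancy of the symbol actually shown.
#' @param k_gain Additional RT benefit (ms) at projected k-point slots
#'   (structural learner only; forced to 0 otherwise).
#' @param first_law_threshold After-0 expectancy level in (0.5, 1) at which
#'   k-tracking switches on (structural learner only).
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind = c("structural", "sequential", "static"),
                         learning_rate = 0.05,
                         anticipation_gain = 110,
                         k_gain = 80,
                         first_law_threshold = 0.8) {
  kind <- match.arg(kind)
  if (learning_rate <= 0 || learning_rate > 1) {
    agl_error("learning_rate must be in (0, 1]", "agl_param_error")
  }
  if (anticipation_gain < 0 || k_gain < 0) {
    agl_error("gains must be >= 0", "agl_param_error")
  }
  if (first_law_threshold <= 0.5 || first_law_threshold >= 1) {
    agl_error("first_law_threshold must be in (0.5, 1)", "agl_param_error")
  }
  if (kind != "structural") k_gain <- 0
  structure(list(kind = kind, learning_rate = learning_rate,
                 anticipation_gain = anticipation_gain, k_gain = k_gain,
                 first_law_threshold = first_law_threshold),
            class = "learner_spec")
}

#' Reaction-time generator parameters
#'
#' The generative model for a single trial: the expected RT is the subject's
#' intercept, reduced proportionally by practice, plus the congruency penalty
#' on incongruent trials, minus the anticipation benefits earned by the
#' learner; the emitted RT is log-normal around that mean and censored at the
#' response deadline (a censored trial is a timeout and is scored incorrect).
#' Non-timeout trials are correct with the per-condition accuracy
#' probability. Defaults are calibrated so that a 22-subject structural
#' cohort reproduces the study's block-1 First-Law cell means
#' (approximately 504 ms congruent, 699 ms incongruent) and its 91% overall
#' accuracy.
#'
#' @param base_mean Population mean of the subject RT intercept (ms).
#' @param subject_sd Between-subject SD of the intercept (ms).
#' @param congruency_penalty Additive RT cost of an incongruent trial (ms).
#' @param practice_decay Proportional reduction of the intercept per 100
#'   trials, in \[0, 1). Default 0: all block-level RT decrease comes from
#'   the learning model, not motor practice.
#' @param noise_sd SD of the Gaussian noise on log-RT.
#' @param deadline Response deadline (ms); draws above it become timeouts.
#' @param accuracy Named numeric vector with elements `congruent` and
#'   `incongruent`: probability that a non-timeout response is correct.
#' @return An object of class `rt_params`.
#' @export
rt_params <- function(base_mean = 549,
                      subject_sd = 80,
                      congruency_penalty = 230,
                      practice_decay = 0,
                      noise_sd = 0.22,
                      deadline = 1000,
                      accuracy = c(congruent = 0.96, incongruent = 0.71)) {
  if (base_mean <= 0) {
    agl_error("base_mean must be positive", "agl_param_error")
  }
  if (subject_sd < 0 || noise_sd < 0) {
    agl_error("standard deviations must be >= 0", "agl_param_error")
  }
  if (practice_decay < 0 || practice_decay >= 1) {
    agl_error("practice_decay must be in [0, 1)", "agl_param_error")
  }
  if (deadline <= 0) agl_error("deadline must be positive", "agl_param_error")
  if (!setequal(names(accuracy), c("congruent", "incongruent")) ||
      any(accuracy < 0 | accuracy > 1)) {
    agl_error("accuracy needs congruent/incongruent probabilities in [0, 1]",
              "agl_param_error")
  }
  structure(list(base_mean = base_mean, subject_sd = subject_sd,
                 congruency_penalty = congruency_penalty,
                 practice_decay = practice_decay, noise_sd = noise_sd,
                 deadline = deadline, accuracy = accuracy),
            class = "rt_params")
}

learner_contexts <- c("start", "after-0", "after-single-1", "after-11")

#' Initialize a learner state
#'
#' @param spec A [learner_spec()].
#' @return A list holding the expectancy traces (one per context and symbol,
#'   initialized at 0) and the k-tracker bookkeeping.
#' @export
learner_init <- function(spec) {
  stopifnot(inherits(spec, "learner_spec"))
  estimates <- matrix(0, nrow = length(learner_contexts), ncol = 2,
                      dimnames = list(learner_contexts, c("0", "1")))
  list(spec = spec, estimates = estimates, position = 0L,
       gate_open = FALSE, last_k = NA_integer_, last_gap = NA_integer_,
       prev_gap = NA_integer_, projected_k = NA_integer_)
}

#' Left context of the upcoming trial
#'
#' @param prev1,prev2 Symbols one and two trials back (`NA` when absent).
#' @return One of `"start"`, `"after-0"`, `"after-single-1"`, `"after-11"`.
#' @export
learner_context <- function(prev1, prev2) {
  ifelse(is.na(prev1), "start",
         ifelse(prev1 == "0", "after-0",
                ifelse(!is.na(prev2) & prev2 == "1", "after-11",
                       "after-single-1")))
}

#' Predictive expectancy of the next symbol
#'
#' Returns the learner's current expectancy for each alphabet symbol in the
#' given context, before any observation. The static learner always returns
#' 0.5 per symbol. The structural learner, when its k-tracker has projected
#' the upcoming position as a k-slot, raises the expectancy of a 1 to at
#' least its acquired after-0 expectancy (its strongest learned
#' association). The state is returned unchanged alongside the probabilities
#' (observations update it via [learner_observe()]).
#'
#' @param state A learner state from [learner_init()].
#' @param context One of the four left contexts (see [learner_context()]).
#' @return A list with `p` (named numeric vector over symbols) and `state`.
#' @export
predictive_probability <- function(state, context) {
  stopifnot(context %in% learner_contexts)
  if (state$spec$kind == "static") {
    return(list(p = c("0" = 0.5, "1" = 0.5), state = state))
  }
  p <- state$estimates[context, ]
  if (state$spec$kind == "structural" && state$gate_open &&
      !is.na(state$projected_k) &&
      state$position + 1L == state$projected_k) {
    p[["1"]] <- max(p[["1"]], state$estimates["after-0", "1"])
  }
  list(p = p, state = state)
}

#' Update a learner state with an observed symbol
#'
#' Applies the exponential trace update for the trial's context and, for the
#' structural learner, advances the online segmentation: a stranded 1 (a 1
#' at the stream start or after a single 1) closes a k-gap, and the gap
#' succession regularities project the next stranded position when they
#' force it.
#'
#' @inheritParams predictive_probability
#' @param symbol The observed symbol, `"0"` or `"1"`.
#' @return The updated state.
#' @export
learner_observe <- function(state, context, symbol) {
  stopifnot(context %in% learner_contexts, symbol %in% c("0", "1"))
  state$position <- state$position + 1L
  if (state$spec$kind == "static") return(state)
  rate <- state$spec$learning_rate
  observed <- as.numeric(c("0", "1") == symbol)
  state$estimates[context, ] <-
    (1 - rate) * state$estimates[context, ] + rate * observed
  if (state$spec$kind == "structural") {
    if (!state$gate_open &&
        state$estimates["after-0", "1"] > state$spec$first_law_threshold) {
      state$gate_open <- TRUE
    }
    stranded <- symbol == "1" && context %in% c("start", "after-single-1")
    if (stranded) {
      if (!is.na(state$last_k)) {
        gap <- state$position - state$last_k
        state$prev_gap <- state$last_gap
        state$last_gap <- gap
        state$projected_k <- NA_integer_
        if (gap == 3L) {
          state$projected_k <- state$position + 5L
        } else if (gap == 5L && !is.na(state$prev_gap) &&
                   state$prev_gap == 5L) {
          state$projected_k <- state$position + 3L
        }
      }
      state$last_k <- state$position
    }
  }
  state
}

#' Per-trial learner trace over a stimulus stream
#'
#' Runs a learner over the trial sequence and records, for every trial, the
#' left context, the expectancy of the symbol actually shown (queried before
#' the observation), and whether the trial sat on a projected k-slot with
#' the tracker gate open. The trace is deterministic given the trials and
#' the spec, and is shared by all simulated subjects.
#'
#' @param trials A trial table from [build_trials()].
#' @param spec A [learner_spec()].
#' @return A [tibble][tibble::tibble] with columns `context`, `p_observed`
#'   and `k_projected`.
#' @export
learner_trace <- function(trials, spec) {
  s <- trials$symbol
  n <- length(s)
  contexts <- learner_context(c(NA, s[-n]), c(NA, NA, s[-c(n - 1, n)]))
  state <- learner_init(spec)
  p_observed <- numeric(n)
  k_projected <- logical(n)
  for (i in seq_len(n)) {
    k_projected[i] <- spec$kind == "structural" && state$gate_open &&
      !is.na(state$projected_k) && state$projected_k == i
    p <- predictive_probability(state, contexts[i])$p
    p_observed[i] <- p[[s[i]]]
    state <- learner_observe(state, contexts[i], s[i])
  }
  tibble::tibble(context = contexts, p_observed = p_observed,
                 k_projected = k_projected)
}

# Expected (pre-noise) RT per trial for one subject.
trial_mu <- function(trials, trace, spec, rt, intercept) {
  n <- nrow(trials)
  mu <- intercept * (1 - rt$practice_decay * seq_len(n) / 100) +
    rt$congruency_penalty * (trials$congruency == "incongruent")
  if (spec$kind != "static") {
    mu <- mu - spec$anticipation_gain * trace$p_observed -
      spec$k_gain * trace$k_projected
  }
  pmax(mu, 100)  # floor: anticipation can never drive the mean RT to zero
}

#' Simulate one subject's responses
#'
#' Draws a subject intercept, computes the expected RT of every trial from
#' the learner trace (see [rt_params()] for the model), and emits censored
#' log-normal RTs with Bernoulli correctness. Fully determined by `seed`.
#'
#' @param trials A trial table from [build_trials()].
#' @param learner A [learner_spec()].
#' @param rt An [rt_params()].
#' @param seed Integer seed for this subject's random stream.
#' @param trace Optional precomputed [learner_trace()] (it only depends on
#'   `trials` and `learner`, so cohort simulation reuses one trace).
#' @return The trial table with added columns `rt_ms` (NA on timeout),
#'   `timeout` and `correct`.
#' @export
simulate_subject <- function(trials, learner, rt, seed, trace = NULL) {
  stopifnot(inherits(learner, "learner_spec"), inherits(rt, "rt_params"))
  if (is.null(trace)) trace <- learner_trace(trials, learner)
  set.seed(seed)
  intercept <- stats::rnorm(1, rt$base_mean, rt$subject_sd)
  if (intercept < 150) intercept <- 150
  mu <- trial_mu(trials, trace, learner, rt, intercept)
  n <- nrow(trials)
  draws <- exp(log(mu) + stats::rnorm(n, 0, rt$noise_sd))
  timeout <- draws > rt$deadline
  acc <- unname(rt$accuracy[trials$congruency])
  correct <- !timeout & stats::runif(n) < acc
  out <- trials
  out$rt_ms <- ifelse(timeout, NA_real_, draws)
  out$timeout <- timeout
  out$correct <- correct
  out
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an independent substream whose seed is derived from the
#' master seed by a fixed prime offset, so cohorts are reproducible and
#' subjects are mutually independent. The default cohort size matches the
#' study (22 children; 330 trials each).
#'
#' @param n_subjects Number of subjects (>= 2; the ANOVA is undefined below
#'   that).
#' @param learner A [learner_spec()].
#' @param rt An [rt_params()].
#' @param master_seed Integer master seed.
#' @param trials Trial table; defaults to the study design
#'   ([build_trials()]).
#' @return A [tibble][tibble::tibble] of class `cohort_dataset`: one row per
#'   subject x trial with the trial columns plus `subject`, `rt_ms`,
#'   `timeout`, `correct`.
#'
#' @examples
#' cohort <- simulate_cohort(n_subjects = 4, master_seed = 7)
#' nrow(cohort)  # 4 * 330
#' @export
simulate_cohort <- function(n_subjects = 22L,
                            learner = learner_spec(),
                            rt = rt_params(),
                            master_seed = 1L,
                            trials = build_trials()) {
  if (n_subjects < 2) {
    agl_error("need at least 2 subjects for within-subject analyses",
              "agl_param_error")
  }
  trace <- learner_trace(trials, learner)
  subject_seeds <- (as.integer(master_seed) + 7919L * seq_len(n_subjects)) %%
    2147483646L + 1L
  rows <- lapply(seq_len(n_subjects), function(s) {
    out <- simulate_subject(trials, learner, rt, subject_seeds[s],
                            trace = trace)
    out$subject <- s
    out
  })
  cohort <- dplyr::bind_rows(rows)
  cohort <- cohort[, c("subject", setdiff(names(cohort), "subject"))]
  class(cohort) <- c("cohort_dataset", class(cohort))
  attr(cohort, "learner") <- learner
  attr(cohort, "rt") <- rt
  attr(cohort, "master_seed") <- as.integer(master_seed)
  cohort
}

cohort_csv_columns <- c("subject", "index", "block", "grammar", "congruency",
                        "a1_target", "a2_target", "a3_target", "is_k",
                        "rt_ms", "timeout", "correct")

#' Write and read cohort datasets as CSV
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort table.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, cohort_csv_columns], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    agl_error(sprintf("cohort file not found: %s", path), "agl_parse_error")
  }
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_integer(), index = readr::col_integer(),
      block = readr::col_integer(), grammar = readr::col_character(),
      congruency = readr::col_character(), a1_target = readr::col_logical(),
      a2_target = readr::col_logical(), a3_target = readr::col_logical(),
      is_k = readr::col_logical(), rt_ms = readr::col_double(),
      timeout = readr::col_logical(), correct = readr::col_logical()),
    progress = FALSE)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    agl_error(sprintf("malformed cohort file: %s at line %d",
                      probs$expected[1], probs$row[1]), "agl_parse_error")
  }
  class(cohort) <- c("cohort_dataset", class(cohort))
  cohort
}
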