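#' Configuration of the modified Simon task
#'
#' The default configuration reproduces the published design: the stimulus
#' stream is generation 12 of the Fibonacci grammar (233 symbols) split
#' contiguously into blocks of 89, 89 and 55 trials, followed by generation 4
#' of the Skip grammar (97 symbols) as block 4, for 330 trials in total.
#' Symbol 0 is shown as a red square (response key 1, on the left of the
#' keyboard) and symbol 1 as a blue square (key 0, on the right). Every sixth
#' trial is incongruent -- the square appears on the side opposite its
#' response key -- and responses time out after 1000 ms.
#'
#' @param fib_generation Fibonacci generation index used for blocks 1-3.
#' @param skip_generation Skip generation index used for block 4.
#' @param block_sizes Integer vector of the four block lengths; the first
#'   three must sum to the Fibonacci generation length and the fourth must
#'   equal the Skip generation length.
#' @param incongruent_period Incongruent trials occur at every multiple of
#'   this trial index (the first incongruent trial is trial
#'   `incongruent_period`).
#' @param response_deadline Response window in ms.
#' @param colour_map Named character vector mapping symbols to colours.
#' @param seed Integer recorded in the config (the trial table itself is
#'   deterministic; the seed feeds the cohort simulator).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(fib_generation = 12L,
                              skip_generation = 4L,
                              block_sizes = c(89L, 89L, 55L, 97L),
                              incongruent_period = 6L,
                              response_deadline = 1000,
                              colour_map = c("0" = "red", "1" = "blue"),
                              seed = 1L) {
  if (length(block_sizes) != 4L || any(block_sizes < 1L)) {
    agl_error("block_sizes must be four positive lengths", "agl_config_error")
  }
  if (incongruent_period < 2L) {
    agl_error("incongruent_period must be >= 2", "agl_config_error")
  }
  if (response_deadline <= 0) {
    agl_error("response_deadline must be positive", "agl_config_error")
  }
  if (!setequal(names(colour_map), c("0", "1"))) {
    agl_error("colour_map needs entries for symbols 0 and 1",
              "agl_config_error")
  }
  structure(list(fib_generation = as.integer(fib_generation),
                 skip_generation = as.integer(skip_generation),
                 block_sizes = as.integer(block_sizes),
                 incongruent_period = as.integer(incongruent_period),
                 response_deadline = response_deadline,
                 colour_map = colour_map,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from a YAML file
#'
#' Recognized keys match the arguments of [experiment_config()]; `learner`
#' and `rt` sub-maps, when present, are passed through to [learner_spec()]
#' and [rt_params()] and attached as attributes.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config` object.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    agl_error(sprintf("config file not found: %s", path), "agl_config_error")
  }
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(experiment_config)))
  args <- cfg[keep]
  if (!is.null(args$colour_map)) args$colour_map <- unlist(args$colour_map)
  if (!is.null(args$block_sizes)) args$block_sizes <- unlist(args$block_sizes)
  out <- do.call(experiment_config, args)
  if (!is.null(cfg$learner)) {
    attr(out, "learner") <- do.call(learner_spec, cfg$learner)
  }
  if (!is.null(cfg$rt)) attr(out, "rt") <- do.call(rt_params, cfg$rt)
  out
}

#' Build the Simon-task trial table
#'
#' Assembles the full trial sequence from the two grammars, assigns colours,
#' response keys, sides and congruency, marks the hierarchical k-points of
#' the Fibonacci stream (Skip trials are never k-points), and fills the
#' analysis-context flags via [label_contexts()]. Sides are fully determined
#' by congruency: a congruent trial shows the square on its response key's
#' side, an incongruent one on the opposite side.
#'
#' @param config An [experiment_config()].
#' @return A [tibble][tibble::tibble] of class `trial_table` with columns
#'   `index`, `block`, `grammar`, `symbol`, `colour`, `correct_key`, `side`,
#'   `congruency`, `is_k`, `a1_target`, `a2_target`, `a3_target`.
#'
#' @examples
#' trials <- build_trials()
#' table(trials$block)
#' sum(trials$congruency == "incongruent")  # 55
#' @export
build_trials <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  fib <- derive(fib_grammar(), config$fib_generation)
  skip <- derive(skip_grammar(), config$skip_generation)
  fib_str <- generation(fib, config$fib_generation)
  skip_str <- generation(skip, config$skip_generation)
  sizes <- config$block_sizes
  if (sum(sizes[1:3]) != nchar(fib_str)) {
    agl_error(sprintf(
      "blocks 1-3 sum to %d but Fibonacci generation %d has %d symbols",
      sum(sizes[1:3]), config$fib_generation, nchar(fib_str)),
      "agl_config_error")
  }
  if (sizes[4] != nchar(skip_str)) {
    agl_error(sprintf(
      "block 4 has %d trials but Skip generation %d has %d symbols",
      sizes[4], config$skip_generation, nchar(skip_str)), "agl_config_error")
  }

  symbol <- c(split_symbols(fib_str), split_symbols(skip_str))
  n <- length(symbol)
  index <- seq_len(n)
  block <- rep(1:4, times = sizes)
  grammar <- rep(c("fib", "skip"), times = c(sum(sizes[1:3]), sizes[4]))
  colour <- unname(config$colour_map[symbol])
  # red square -> key 1 (left); blue square -> key 0 (right)
  correct_key <- ifelse(symbol == "0", "key1", "key0")
  key_side <- c(key1 = "left", key0 = "right")
  congruency <- ifelse(index %% config$incongruent_period == 0L,
                       "incongruent", "congruent")
  side <- ifelse(congruency == "congruent",
                 key_side[correct_key],
                 ifelse(key_side[correct_key] == "left", "right", "left"))

  fib_classes <- classify_points(fib, config$fib_generation)$point_class
  is_k <- c(fib_classes == "k", rep(FALSE, sizes[4]))

  trials <- tibble::tibble(index = index, block = block, grammar = grammar,
                           symbol = symbol, colour = colour,
                           correct_key = correct_key, side = unname(side),
                           congruency = congruency, is_k = is_k,
                           a1_target = FALSE, a2_target = FALSE,
                           a3_target = FALSE)
  trials <- label_contexts(trials)
  class(trials) <- c("trial_table", class(trials))
  attr(trials, "config") <- config
  trials
}

#' Fill the analysis-context flags of a trial table
#'
#' The three analyses target specific local contexts, read in presentation
#' order across block boundaries: `a1_target` marks blue trials immediately
#' preceded by a red one (First-Law continuations), `a2_target` marks red
#' trials immediately preceded by two blues (Second-Law continuations), and
#' `a3_target` marks blue trials immediately preceded by a red-blue pair --
#' in the Fibonacci stream these are exactly the k-points with a preceding
#' 0 1. Trials 1-2 can never be a2/a3 targets and trial 1 never an a1 target.
#'
#' @param trials A trial table in presentation order.
#' @return The same table with the `a1_target`, `a2_target` and `a3_target`
#'   columns recomputed.
#' @export
label_contexts <- function(trials) {
  s <- trials$symbol
  n <- length(s)
  lag1 <- c(NA, s[-n])
  lag2 <- c(NA, NA, s[-c(n - 1, n)])
  trials$a1_target <- !is.na(lag1) & s == "1" & lag1 == "0"
  trials$a2_target <- !is.na(lag2) & s == "0" & lag1 == "1" & lag2 == "1"
  trials$a3_target <- !is.na(lag2) & s == "1" & lag1 == "1" & lag2 == "0"
  trials
}

trial_columns <- c("index", "block", "grammar", "symbol", "colour",
                   "correct_key", "side", "congruency", "is_k",
                   "a1_target", "a2_target", "a3_target")

#' Write and read trial tables as CSV
#'
#' One row per trial with a fixed header; `read_trials(write_trials(x))`
#' round-trips field-for-field. On read, the symbol column is re-validated
#' against the Three Laws and a warning is raised if the sequence is
#' ungrammatical (e.g. contains a red-red transition).
#'
#' @param trials A trial table from [build_trials()].
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the trial table.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, trial_columns], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    agl_error(sprintf("trial file not found: %s", path), "agl_parse_error")
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      index = readr::col_integer(), block = readr::col_integer(),
      grammar = readr::col_character(), symbol = readr::col_character(),
      colour = readr::col_character(), correct_key = readr::col_character(),
      side = readr::col_character(), congruency = readr::col_character(),
      is_k = readr::col_logical(), a1_target = readr::col_logical(),
      a2_target = readr::col_logical(), a3_target = readr::col_logical()),
    progress = FALSE)
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    agl_error(sprintf("malformed trial file: %s at line %d",
                      probs$expected[1], probs$row[1]), "agl_parse_error")
  }
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    agl_error(sprintf("trial file lacks columns: %s",
                      paste(missing_cols, collapse = ", ")),
              "agl_parse_error")
  }
  report <- validate_three_laws(paste(trials$symbol, collapse = ""))
  if (!is_grammatical(report)) {
    agl_warn(sprintf(
      "symbol sequence violates the Three Laws (%d x '00', %d x '111')",
      length(report$first_law_violations),
      length(report$second_law_violations)), "agl_law_violation_warning")
  }
  class(trials) <- c("trial_table", class(trials))
  trials
}
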