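#' Define a deterministic context-free L-system
#'
#' An L-system (Lindenmayer system) is a rewriting grammar in which every
#' symbol of a string is rewritten simultaneously at each derivational step
#' and there is no terminal/non-terminal distinction: every alphabet symbol
#' has exactly one rewrite rule and every symbol can (and must) be rewritten.
#'
#' @param name Short label for the grammar.
#' @param alphabet Character vector of single-character symbols.
#' @param rules Named list or named character vector mapping each alphabet
#'   symbol to its (non-empty) right-hand side, written as a string over the
#'   alphabet, e.g. `list("0" = "1", "1" = "01")`.
#'
#' @return An object of class `lsystem_grammar` with elements `name`,
#'   `alphabet` and `rules` (a named character vector).
#'
#' @examples
#' fib <- lsystem_grammar("fib", c("0", "1"), list("0" = "1", "1" = "01"))
#' rewrite_generation(fib, "01101")
#'
#' @seealso [fib_grammar()], [skip_grammar()], [derive()]
#' @export
lsystem_grammar <- function(name, alphabet, rules) {
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
    agl_error("alphabet must be distinct single-character symbols",
              "agl_alphabet_error")
  }
  rules <- vapply(rules, as.character, character(1))
  if (!setequal(names(rules), alphabet) || length(rules) != length(alphabet)) {
    agl_error("every alphabet symbol needs exactly one rule",
              "agl_alphabet_error")
  }
  rules <- rules[alphabet]
  if (any(nchar(rules) == 0L)) {
    agl_error("rule right-hand sides must be non-empty", "agl_alphabet_error")
  }
  rhs_symbols <- unique(unlist(strsplit(rules, "", fixed = TRUE)))
  if (!all(rhs_symbols %in% alphabet)) {
    agl_error(
      sprintf("rule right-hand sides use symbols outside the alphabet: %s",
              paste(setdiff(rhs_symbols, alphabet), collapse = ", ")),
      "agl_alphabet_error")
  }
  structure(list(name = name, alphabet = alphabet, rules = rules),
            class = "lsystem_grammar")
}

#' @export
print.lsystem_grammar <- function(x, ...) {
  cat(sprintf("L-system grammar '%s' over {%s}\n", x$name,
              paste(x$alphabet, collapse = ", ")))
  for (s in x$alphabet) cat(sprintf("  %s -> %s\n", s, x$rules[[s]]))
  invisible(x)
}

#' Built-in grammars
#'
#' `fib_grammar()` is the Fibonacci grammar (0 -> 1, 1 -> 01), an asymmetric
#' L-system whose generation lengths follow the Fibonacci numbers.
#' `skip_grammar()` is its "expansion" (0 -> 01, 1 -> 01101), in which each
#' symbol rewrites as a non-subsequent Fibonacci generation: the surface
#' transition laws are preserved but the constituent structure -- and with it
#' the existence of k-points -- is destroyed.
#'
#' @return An [lsystem_grammar()] object.
#' @export
fib_grammar <- function() {
  lsystem_grammar("fib", c("0", "1"), list("0" = "1", "1" = "01"))
}

#' @rdname fib_grammar
#' @export
skip_grammar <- function() {
  lsystem_grammar("skip", c("0", "1"), list("0" = "01", "1" = "01101"))
}

#' Load a grammar definition from a YAML config file
#'
#' The file must provide `name`, `alphabet` (list of symbols) and `rules`
#' (a map from symbol to right-hand-side string). The strings `"fib"` and
#' `"skip"` are also accepted in place of a path and return the built-ins.
#'
#' @param path Path to a YAML file, or `"fib"` / `"skip"`.
#' @return An [lsystem_grammar()] object.
#' @export
read_grammar <- function(path) {
  if (identical(path, "fib")) return(fib_grammar())
  if (identical(path, "skip")) return(skip_grammar())
  if (!file.exists(path)) {
    agl_error(sprintf("grammar file not found: %s", path), "agl_config_error")
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "alphabet", "rules")) {
    if (is.null(cfg[[field]])) {
      agl_error(sprintf("grammar config is missing '%s'", field),
                "agl_config_error")
    }
  }
  lsystem_grammar(cfg$name, unlist(cfg$alphabet), cfg$rules)
}

split_symbols <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

check_symbols <- function(grammar, symbols) {
  bad <- which(!(symbols %in% grammar$alphabet))
  if (length(bad)) {
    agl_error(
      sprintf("symbol '%s' at position %d is not in the alphabet {%s}",
              symbols[bad[1]], bad[1],
              paste(grammar$alphabet, collapse = ", ")),
      "agl_alphabet_error")
  }
  invisible(TRUE)
}

#' Apply one parallel derivational step
#'
#' Rewrites every symbol of `seq` simultaneously through the grammar's rules
#' and records, for every output position, the input position it came from.
#' The parent spans partition the output string contiguously and in order.
#'
#' @param grammar An [lsystem_grammar()].
#' @param seq Symbol string over the grammar's alphabet.
#' @return A list with `sequence` (the rewritten string) and `parent`
#'   (integer vector: for each output position, the 1-based source position).
#'
#' @examples
#' rewrite_generation(fib_grammar(), "0")       # "1"
#' rewrite_generation(fib_grammar(), "01101")   # "10101101"
#' @export
rewrite_generation <- function(grammar, seq) {
  symbols <- split_symbols(seq)
  check_symbols(grammar, symbols)
  images <- grammar$rules[symbols]
  widths <- nchar(images)
  list(sequence = paste(images, collapse = ""),
       parent = rep(seq_along(symbols), widths))
}

#' Derive n generations of an L-system
#'
#' Starting from the axiom (generation 0), applies [rewrite_generation()]
#' `n` times, materializing every generation together with its parent links.
#' For the Fibonacci grammar from axiom `"0"`, generation lengths satisfy the
#' Fibonacci recurrence; generation 12 has 233 symbols. For the Skip grammar,
#' generation 4 has 97 symbols.
#'
#' @param grammar An [lsystem_grammar()].
#' @param n Number of derivational steps (>= 0). Capped at 30 to bound
#'   memory (Fibonacci generation 30 is about 1.3M symbols).
#' @param axiom Starting string; defaults to `"0"`, which is the convention
#'   under which the grammar's printed generation lengths come out.
#' @return An object of class `lsystem_derivation`: a list with `grammar`,
#'   `axiom`, `generations` (character vector of length `n + 1`, element 1 =
#'   the axiom) and `parent_links` (list; element `g` maps each position of
#'   generation `g` to its parent position in generation `g - 1`).
#'
#' @examples
#' d <- derive(fib_grammar(), 12)
#' nchar(generation(d, 12))  # 233
#' @export
derive <- function(grammar, n, axiom = "0") {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n)) {
    agl_error("n must be a single non-negative integer", "agl_argument_error")
  }
  if (n > 30) {
    agl_error("n is capped at 30 generations", "agl_argument_error")
  }
  if (!nzchar(axiom)) {
    agl_error("axiom must be non-empty", "agl_argument_error")
  }
  check_symbols(grammar, split_symbols(axiom))
  generations <- character(n + 1L)
  generations[1L] <- axiom
  parent_links <- vector("list", n)
  if (n > 0) {
    for (g in seq_len(n)) {
      step <- rewrite_generation(grammar, generations[g])
      generations[g + 1L] <- step$sequence
      parent_links[[g]] <- step$parent
    }
  }
  structure(list(grammar = grammar, axiom = axiom,
                 generations = generations, parent_links = parent_links),
            class = "lsystem_derivation")
}

#' @export
print.lsystem_derivation <- function(x, ...) {
  n <- length(x$generations) - 1L
  cat(sprintf("Derivation of '%s' from axiom \"%s\": %d step%s\n",
              x$grammar$name, x$axiom, n, if (n == 1) "" else "s"))
  lens <- nchar(x$generations)
  cat("  generation lengths:", paste(lens, collapse = " "), "\n")
  show <- min(n, 6L)
  for (g in 0:show) {
    s <- x$generations[g + 1L]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  g%-2d %s\n", g, s))
  }
  if (n > show) cat("  ...\n")
  invisible(x)
}

n_generations <- function(derivation) length(derivation$generations) - 1L

check_gen_index <- function(derivation, gen) {
  if (!is.numeric(gen) || length(gen) != 1L || is.na(gen) ||
      gen != round(gen) || gen < 0 || gen > n_generations(derivation)) {
    agl_error(sprintf("generation index must be in 0..%d",
                      n_generations(derivation)), "agl_argument_error")
  }
  invisible(TRUE)
}

#' Extract one generation of a derivation
#'
#' @param derivation An object from [derive()].
#' @param gen Generation index; 0 is the axiom.
#' @return The generation as a single string.
#' @export
generation <- function(derivation, gen) {
  check_gen_index(derivation, gen)
  derivation$generations[gen + 1L]
}

#' All generations of a derivation
#'
#' @inheritParams generation
#' @return Character vector; element `i` is generation `i - 1`.
#' @export
generations <- function(derivation) derivation$generations

#' Symbol counts of one generation
#'
#' In the Fibonacci grammar the counts themselves are self-similar: the
#' number of 1s in generation n equals the length of generation n - 1, and
#' the number of 0s equals the number of 1s in generation n - 1.
#'
#' @inheritParams generation
#' @return Named integer vector of counts, one per alphabet symbol, summing
#'   to the generation length.
#' @export
symbol_counts <- function(derivation, gen) {
  check_gen_index(derivation, gen)
  symbols <- split_symbols(generation(derivation, gen))
  counts <- table(factor(symbols, levels = derivation$grammar$alphabet))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
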