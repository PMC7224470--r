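#' Validate the Three Laws on a symbol string
#'
#' The surface transition regularities of the Fibonacci and Skip grammars:
#' a 0 is always followed by a 1 (First Law: "00" never occurs), two 1s are
#' always followed by a 0 (Second Law: "111" never occurs), and a single 1
#' may be followed by either symbol (Third Law: the ambiguity). A string is
#' grammatical under the laws iff both violation lists are empty.
#'
#' Each position also receives a predictability label derived from its left
#' context: `forced_one` when the predecessor is 0, `forced_zero` when the
#' two predecessors are 1 1, `ambiguous` when the predecessor is a single 1
#' (preceded by 0 or by the string start), and `undefined` for position 1,
#' which has no left context.
#'
#' @param s String over the alphabet \{0, 1\}.
#' @return A list of class `law_report` with `first_law_violations`
#'   (positions where "00" starts), `second_law_violations` (positions where
#'   "111" starts) and `position_labels` (character vector, one label per
#'   position).
#'
#' @examples
#' validate_three_laws("001")   # First Law violation at position 1
#' validate_three_laws("0111")  # Second Law violation at position 2
#' @export
validate_three_laws <- function(s) {
  symbols <- split_symbols(s)
  bad <- which(!(symbols %in% c("0", "1")))
  if (length(bad)) {
    agl_error(sprintf("symbol '%s' at position %d is not 0 or 1",
                      symbols[bad[1]], bad[1]), "agl_alphabet_error")
  }
  n <- length(symbols)
  is0 <- symbols == "0"
  is1 <- !is0
  first_law <- which(is0[-n] & is0[-1])
  second_law <- integer(0)
  if (n >= 3) {
    second_law <- which(is1[1:(n - 2)] & is1[2:(n - 1)] & is1[3:n])
  }
  labels <- rep("undefined", n)
  if (n >= 2) {
    prev0 <- is0[1:(n - 1)]
    prev1 <- is1[1:(n - 1)]
    # predecessor is a "single" 1 when it is itself preceded by 0 or by the
    # string start; two 1s in a row force a 0 next
    prevprev1 <- c(FALSE, if (n >= 3) is1[1:(n - 2)] else logical(0))
    labels[-1][prev0] <- "forced_one"
    labels[-1][prev1 & !prevprev1] <- "ambiguous"
    labels[-1][prev1 & prevprev1] <- "forced_zero"
  }
  structure(list(first_law_violations = as.integer(first_law),
                 second_law_violations = as.integer(second_law),
                 position_labels = labels),
            class = "law_report")
}

#' @export
print.law_report <- function(x, ...) {
  ok <- length(x$first_law_violations) == 0 &&
    length(x$second_law_violations) == 0
  cat(sprintf("Three-Laws report over %d positions: %s\n",
              length(x$position_labels),
              if (ok) "grammatical" else "VIOLATIONS"))
  if (length(x$first_law_violations)) {
    cat("  '00' starting at:", paste(x$first_law_violations, collapse = " "),
        "\n")
  }
  if (length(x$second_law_violations)) {
    cat("  '111' starting at:", paste(x$second_law_violations, collapse = " "),
        "\n")
  }
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$position_labels)),
                                 table(x$position_labels)), collapse = " "),
      "\n")
  invisible(x)
}

#' Is a string grammatical under the Three Laws?
#'
#' @param x A string or a `law_report`.
#' @return `TRUE` iff the string contains neither "00" nor "111".
#' @export
is_grammatical <- function(x) {
  report <- if (inherits(x, "law_report")) x else validate_three_laws(x)
  length(report$first_law_violations) == 0 &&
    length(report$second_law_violations) == 0
}

#' Classify every position of a generation as k / n / s / plain 1 / zero
#'
#' Hierarchical point classification over the derivation tree. A *k-point*
#' is a 1 immediately dominated by a 0 whose children (its rule image in the
#' next generation) are exactly 0 1; an *n-point* is a 1 immediately
#' dominated by a k-point; an *s-point* is a 1 immediately dominated by an
#' n- or s-point. Every other 1 is a `plain_one` and every 0 is `zero`.
#' In the Fibonacci grammar every 1 is exactly one of k/n/s; in the Skip
#' grammar the downward clause fails everywhere (a 1 rewrites as the
#' 5-symbol block 01101, never as 0 1), so every 1 is a plain 1 -- the
#' structural dissociation between the two grammars.
#'
#' Classification of generation g needs the point classes of generation
#' g - 1, so classes are built iteratively from generation 1 upward. For the
#' final generation of the derivation the children are obtained from a
#' one-step lookahead rewrite.
#'
#' @param derivation An [lsystem_derivation][derive()].
#' @param gen Generation index, >= 1 (the axiom has no parent links).
#' @return A [tibble][tibble::tibble] with one row per position: `gen`,
#'   `pos` (1-based), `symbol` and `point_class`.
#'
#' @examples
#' d <- derive(fib_grammar(), 5)
#' subset(classify_points(d, 5), point_class == "k")  # positions 1 and 6
#' @export
classify_points <- function(derivation, gen) {
  check_gen_index(derivation, gen)
  if (gen < 1) {
    agl_error("gen must be >= 1: the axiom has no parent links",
              "agl_no_parent_error")
  }
  grammar <- derivation$grammar
  n_gens <- n_generations(derivation)

  # axiom classes seed the recursion: a lone starting 1 could only be
  # classified by dominance downward, which the k test below covers
  prev_symbols <- split_symbols(derivation$generations[1L])
  prev_classes <- ifelse(prev_symbols == "0", "zero", "plain_one")

  for (g in seq_len(gen)) {
    symbols <- split_symbols(derivation$generations[g + 1L])
    parent <- derivation$parent_links[[g]]
    parent_symbol <- prev_symbols[parent]
    parent_class <- prev_classes[parent]
    if (g < n_gens) {
      # parent spans are contiguous and in order, so each position's child
      # image is a substring of the next generation
      widths <- tabulate(derivation$parent_links[[g + 1L]],
                         nbins = length(symbols))
      ends <- cumsum(widths)
      child_image <- substring(derivation$generations[g + 2L],
                               ends - widths + 1L, ends)
    } else {
      # one-step lookahead: children of a position are its rule image
      child_image <- unname(grammar$rules[symbols])
    }
    classes <- rep("plain_one", length(symbols))
    classes[symbols == "0"] <- "zero"
    one <- symbols == "1"
    is_k <- one & parent_symbol == "0" & child_image == "01"
    classes[is_k] <- "k"
    classes[one & !is_k & parent_class == "k"] <- "n"
    classes[one & !is_k & parent_class %in% c("n", "s")] <- "s"
    prev_symbols <- symbols
    prev_classes <- classes
  }
  tibble::tibble(gen = gen, pos = seq_along(prev_symbols),
                 symbol = prev_symbols, point_class = prev_classes)
}

#' k-point positions by greedy string segmentation
#'
#' Chunks a grammatical string left-to-right into \[01\] bigrams (the unit
#' the First Law makes fully predictable); every 1 that cannot start a chunk
#' is stranded, and the stranded 1s are exactly the k-points of a Fibonacci
#' string. An equivalent characterization -- the second 1 of every 11 bigram,
#' plus position 1 when the string starts with 1 -- holds and is asserted in
#' the test suite, but the greedy chunking is the definition.
#'
#' @param s String over \{0, 1\}, grammatical under the Three Laws.
#' @return Strictly ascending integer vector of stranded-1 positions.
#'
#' @examples
#' k_positions_by_segmentation("011")       # 3
#' k_positions_by_segmentation("10101101")  # 1 6
#' k_positions_by_segmentation("0101")      # integer(0)
#' @export
k_positions_by_segmentation <- function(s) {
  report <- validate_three_laws(s)
  if (!is_grammatical(report)) {
    agl_error("string violates the Three Laws; cannot segment",
              "agl_law_violation_error")
  }
  symbols <- split_symbols(s)
  n <- length(symbols)
  stranded <- integer(0)
  i <- 1L
  while (i <= n) {
    if (symbols[i] == "0") {
      i <- i + 2L  # First Law guarantees a 1 follows (or the string ends)
    } else {
      stranded <- c(stranded, i)
      i <- i + 1L
    }
  }
  stranded
}

#' k-skeleton of a string
#'
#' An abstraction of a string to its length plus the ascending positions of
#' its k-points: enough, in the Fibonacci grammar, to reconstruct the full
#' string (see [reconstruct_from_skeleton()]).
#'
#' @param k_positions Strictly ascending 1-based positions.
#' @param length Total symbol count.
#' @return An object of class `k_skeleton`.
#' @export
k_skeleton <- function(k_positions, length) {
  k_positions <- as.integer(k_positions)
  length <- as.integer(length)
  if (length < 0) agl_error("length must be >= 0", "agl_argument_error")
  if (is.unsorted(k_positions, strictly = TRUE)) {
    agl_error("k positions must be strictly ascending", "agl_argument_error")
  }
  if (any(k_positions < 1L | k_positions > length)) {
    agl_error("k positions must lie within 1..length", "agl_argument_error")
  }
  structure(list(length = length, k_positions = k_positions),
            class = "k_skeleton")
}

#' @export
print.k_skeleton <- function(x, ...) {
  cat(sprintf("k-skeleton: %d slots, k at {%s}\n", x$length,
              paste(x$k_positions, collapse = ", ")))
  cat(" ", format_skeleton(x), "\n")
  invisible(x)
}

format_skeleton <- function(sk) {
  slots <- rep("_", sk$length)
  slots[sk$k_positions] <- "1"
  paste(slots, collapse = "")
}

#' @rdname k_skeleton
#' @param s A grammatical symbol string whose skeleton is extracted via
#'   [k_positions_by_segmentation()].
#' @export
k_skeleton_of <- function(s) {
  k_skeleton(k_positions_by_segmentation(s), nchar(s))
}

#' Read and write skeleton files
#'
#' Plain-text notation with `1` at k-point positions and `_` for unknown
#' slots, e.g. `1____1__` for an 8-slot skeleton with k at positions 1 and 6.
#'
#' @param sk A [k_skeleton()].
#' @param path File path.
#' @return `read_skeleton()` returns a `k_skeleton`; `write_skeleton()`
#'   returns `path` invisibly.
#' @export
write_skeleton <- function(sk, path) {
  writeLines(format_skeleton(sk), path)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  slots <- split_symbols(line)
  bad <- which(!(slots %in% c("1", "_")))
  if (length(bad)) {
    agl_error(sprintf("skeleton files use only '1' and '_'; found '%s' at %d",
                      slots[bad[1]], bad[1]), "agl_parse_error")
  }
  k_skeleton(which(slots == "1"), length(slots))
}

#' Successive k-point gaps and their succession regularities
#'
#' `k_gap_sequence()` returns the successive position differences of a
#' skeleton's k-points. In Fibonacci strings every gap is 3 or 5 symbols and
#' the gap succession mirrors the Three Laws one level up (self-similarity):
#' a gap of 3 is always followed by a gap of 5; a gap of 5 is followed by 3
#' or 5; two 5s in a row are always followed by a 3.
#' `validate_gap_succession()` returns the indices (into the gap list) where
#' those rules are broken.
#'
#' @param sk A [k_skeleton()] or an ascending integer vector of positions.
#' @return `k_gap_sequence()`: integer vector of gaps (empty when fewer than
#'   two k-points). `validate_gap_succession()`: integer vector of violation
#'   indices (empty when the succession rules hold).
#'
#' @examples
#' k_gap_sequence(k_skeleton_of("10101101"))  # 5
#' validate_gap_succession(c(3, 5, 5, 3))     # integer(0)
#' validate_gap_succession(c(3, 3))           # 2
#' @export
k_gap_sequence <- function(sk) {
  positions <- if (inherits(sk, "k_skeleton")) sk$k_positions else
    as.integer(sk)
  if (length(positions) < 2) return(integer(0))
  diff(positions)
}

#' @rdname k_gap_sequence
#' @param gaps Integer vector of successive gaps.
#' @export
validate_gap_succession <- function(gaps) {
  gaps <- as.integer(gaps)
  violations <- integer(0)
  for (i in seq_along(gaps)[-1]) {
    if (gaps[i - 1] == 3 && gaps[i] != 5) {
      violations <- c(violations, i)
    } else if (gaps[i - 1] == 5) {
      if (i >= 3 && gaps[i - 2] == 5) {
        if (gaps[i] != 3) violations <- c(violations, i)
      } else if (!gaps[i] %in% c(3L, 5L)) {
        violations <- c(violations, i)
      }
    }
  }
  violations
}

#' Reconstruct a Fibonacci string from its k-skeleton
#'
#' The effective procedure that makes k-points structurally valuable: a k is
#' always followed by the constituent \[0 1\], and when the next k is 5
#' symbols away the two remaining slots before it must again be 0 1. A
#' two-slot prefix before the first k is likewise forced to 0 1. Only those
#' forced cases are accepted: a prefix of any other length, a gap outside
#' \{3, 5\}, or more than two trailing slots after the last k leave slots
#' undetermined and raise an error rather than guess.
#'
#' @param sk A [k_skeleton()].
#' @return The reconstructed symbol string, with 1s exactly at the k
#'   positions plus the forced 1s. Round-trip:
#'   `k_positions_by_segmentation()` of the output recovers
#'   `sk$k_positions`.
#'
#' @examples
#' reconstruct_from_skeleton(k_skeleton(c(1, 6), 8))  # "10101101"
#' @export
reconstruct_from_skeleton <- function(sk) {
  stopifnot(inherits(sk, "k_skeleton"))
  ks <- sk$k_positions
  if (length(ks) == 0) {
    agl_error("skeleton has no k-points; nothing forces any slot",
              "agl_invalid_skeleton_error")
  }
  gaps <- k_gap_sequence(ks)
  if (any(!gaps %in% c(3L, 5L))) {
    agl_error(sprintf("k gaps must be 3 or 5 symbols; found %s",
                      paste(setdiff(gaps, c(3L, 5L)), collapse = ", ")),
              "agl_invalid_skeleton_error")
  }
  prefix <- ks[1] - 1L
  if (!prefix %in% c(0L, 2L)) {
    agl_error(sprintf(
      "prefix of %d slot(s) before the first k is not forced (must be 0 or 2)",
      prefix), "agl_invalid_skeleton_error")
  }
  suffix <- sk$length - ks[length(ks)]
  if (suffix > 2L) {
    agl_error(sprintf(
      "%d trailing slots after the last k cannot be determined", suffix),
      "agl_ambiguous_suffix_error")
  }
  out <- rep(NA_character_, sk$length)
  out[ks] <- "1"
  if (prefix == 2L) out[1:2] <- c("0", "1")
  for (i in seq_along(ks)) {
    p <- ks[i]
    fill <- p + 1:2
    fill <- fill[fill <= sk$length]
    out[fill] <- c("0", "1")[seq_along(fill)]
    if (i < length(ks) && gaps[i] == 5L) {
      out[p + 3:4] <- c("0", "1")
    }
  }
  paste(out, collapse = "")
}
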