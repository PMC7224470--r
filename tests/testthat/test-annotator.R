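test_that("Three-Laws violations are located exactly", {
  r <- validate_three_laws("001")
  expect_identical(r$first_law_violations, 1L)
  expect_identical(r$second_law_violations, integer(0))
  r <- validate_three_laws("0111")
  expect_identical(r$second_law_violations, 2L)
  expect_false(is_grammatical("00"))
  expect_true(is_grammatical("0101101"))
  expect_error(validate_three_laws("01x"), class = "agl_alphabet_error")
})

test_that("predictability labels follow the left context", {
  labels <- validate_three_laws("0110101")$position_labels
  expect_identical(labels,
                   c("undefined", "forced_one", "ambiguous", "forced_zero",
                     "forced_one", "ambiguous", "forced_one"))
  # a string-initial 1 leaves position 2 ambiguous (single-1 context)
  expect_identical(validate_three_laws("10")$position_labels,
                   c("undefined", "ambiguous"))
  expect_identical(validate_three_laws("1")$position_labels, "undefined")
})

test_that("generated generations and their junction respect the Three Laws", {
  fib <- derive(fib_grammar(), 20)
  for (n in 0:20) expect_true(is_grammatical(generation(fib, n)))
  skip <- derive(skip_grammar(), 6)
  for (n in 0:6) expect_true(is_grammatical(generation(skip, n)))
  junction <- paste0(generation(fib, 12), generation(skip, 4))
  expect_true(is_grammatical(junction))
})

test_that("hierarchical point classes match the worked derivations", {
  fib <- derive(fib_grammar(), 5)
  g4 <- classify_points(fib, 4)
  expect_identical(g4$pos[g4$point_class == "k"], 3L)
  g5 <- classify_points(fib, 5)
  expect_identical(g5$pos[g5$point_class == "k"], c(1L, 6L))
  # every 1 in a Fibonacci generation is exactly one of k/n/s
  expect_true(all(g5$point_class[g5$symbol == "1"] %in% c("k", "n", "s")))
  expect_true(all(g5$point_class[g5$symbol == "0"] == "zero"))
  expect_error(classify_points(fib, 0), class = "agl_no_parent_error")
})

test_that("Skip has no k-, n- or s-points although segmentation strands 1s", {
  skip <- derive(skip_grammar(), 6)
  for (n in 1:6) {
    classes <- classify_points(skip, n)$point_class
    expect_false(any(classes %in% c("k", "n", "s")))
    if (n >= 2) {
      expect_gt(length(k_positions_by_segmentation(generation(skip, n))), 0)
    }
  }
})

test_that("greedy segmentation strands the k-point 1s", {
  expect_identical(k_positions_by_segmentation("011"), 3L)
  expect_identical(k_positions_by_segmentation("10101101"), c(1L, 6L))
  expect_identical(k_positions_by_segmentation("0101"), integer(0))
  expect_error(k_positions_by_segmentation("001"),
               class = "agl_law_violation_error")
})

test_that("hierarchical and segmentation k-definitions agree on Fib 2..20", {
  fib <- derive(fib_grammar(), 20)
  for (n in 2:20) {
    s <- generation(fib, n)
    seg <- k_positions_by_segmentation(s)
    cls <- classify_points(fib, n)
    expect_identical(cls$pos[cls$point_class == "k"], seg)
    # equivalent formulation: second 1 of every 11 bigram, plus position 1
    # when the string starts with 1
    symbols <- strsplit(s, "")[[1]]
    alt <- which(symbols == "1" &
                   c("", symbols[-length(symbols)]) == "1")
    if (symbols[1] == "1") alt <- c(1L, alt)
    expect_identical(seg, as.integer(alt))
  }
})

test_that("k-gaps and their succession regularities behave", {
  fib <- derive(fib_grammar(), 20)
  expect_identical(k_gap_sequence(k_skeleton_of(generation(fib, 5))), 5L)
  expect_identical(validate_gap_succession(c(3, 5, 5, 3)), integer(0))
  expect_identical(validate_gap_succession(c(3, 3)), 2L)
  expect_identical(validate_gap_succession(c(5, 5, 5)), 3L)
  expect_identical(validate_gap_succession(integer(0)), integer(0))
  for (n in 5:20) {
    gaps <- k_gap_sequence(k_skeleton_of(generation(fib, n)))
    expect_true(all(gaps %in% c(3L, 5L)))
    expect_identical(validate_gap_succession(gaps), integer(0))
  }
})

test_that("k-gaps of generation 12 are not a short repeating cycle", {
  gaps <- k_gap_sequence(k_skeleton_of(generation(derive(fib_grammar(), 12),
                                                  12)))
  for (p in 1:4) {
    shifted <- gaps[(p + 1):length(gaps)]
    expect_false(all(shifted == gaps[1:length(shifted)]))
  }
})

test_that("skeleton reconstruction reproduces the worked example", {
  expect_identical(reconstruct_from_skeleton(k_skeleton(c(1, 6), 8)),
                   "10101101")
  expect_identical(reconstruct_from_skeleton(k_skeleton(1, 3)), "101")
  expect_error(reconstruct_from_skeleton(k_skeleton(c(1, 5), 9)),
               class = "agl_invalid_skeleton_error")
  expect_error(reconstruct_from_skeleton(k_skeleton(c(2, 5), 7)),
               class = "agl_invalid_skeleton_error")  # prefix of 1 slot
  expect_error(reconstruct_from_skeleton(k_skeleton(1, 6)),
               class = "agl_ambiguous_suffix_error")
  expect_error(k_skeleton(c(5, 1), 8), class = "agl_argument_error")
})

test_that("skeleton extraction and reconstruction round-trip on Fib 5..15", {
  fib <- derive(fib_grammar(), 15)
  for (n in 5:15) {
    s <- generation(fib, n)
    sk <- k_skeleton_of(s)
    expect_identical(reconstruct_from_skeleton(sk), s)
    expect_identical(k_positions_by_segmentation(reconstruct_from_skeleton(sk)),
                     sk$k_positions)
  }
})

test_that("skeleton files round-trip in the underscore notation", {
  path <- withr::local_tempfile(fileext = ".txt")
  sk <- k_skeleton(c(1, 6), 8)
  write_skeleton(sk, path)
  expect_identical(readLines(path), "1____1__")
  back <- read_skeleton(path)
  expect_identical(back$k_positions, sk$k_positions)
  expect_identical(back$length, sk$length)
  writeLines("1_x_", path)
  expect_error(read_skeleton(path), class = "agl_parse_error")
})
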