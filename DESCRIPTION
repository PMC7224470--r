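Package: fibagl
Title: Sequential and Hierarchical Learning with Fibonacci L-System Grammars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying implicit sequential versus hierarchical
    learning with Lindenmayer-system artificial grammars. Implements parallel
    string rewriting with derivation-tree parent links for the Fibonacci
    grammar (0 -> 1, 1 -> 01) and the Skip grammar (0 -> 01, 1 -> 01101),
    hierarchical point classification (k-, n- and s-points), string-level
    k-point identification by greedy bigram segmentation, the surface
    transition laws and their validation, k-gap succession checks, and
    reconstruction of a string from its k-point skeleton. On top of the
    grammar machinery it builds the 330-trial modified Simon-task sequence
    (three Fibonacci blocks plus one Skip block with a periodic incongruency
    schedule), simulates learner cohorts (static, sequential transitional-
    probability, and structure-tracking learners) with censored log-normal
    reaction times, and runs the three repeated-measures analyses
    (within-subject ANOVA with partial eta squared and Bonferroni-corrected
    pairwise post-hocs) that probe First-Law learning, Second-Law learning,
    and sensitivity to k-points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
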