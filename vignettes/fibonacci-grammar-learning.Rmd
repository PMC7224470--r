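---
title: "Sequential vs hierarchical learning with L-system grammars: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential vs hierarchical learning with L-system grammars: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibagl)
```

## The problem

Serial reaction time (SRT) experiments show that people implicitly learn
transition regularities in a stimulus stream. Whether they *also* build
hierarchical representations is much harder to demonstrate, because in most
artificial grammars any advantage at a "structural" position can be
re-explained by surface statistics. `fibagl` implements a design that
separates the two: two Lindenmayer systems that share their surface
transition laws but differ in constituent structure, embedded in a modified
Simon task, plus a simulated cohort and the repeated-measures analyses that
probe each kind of learning.

An L-system rewrites every symbol of a string simultaneously at each step;
there are no terminals, so derivation never halts and each step yields a new
*generation*. The two grammars here are

* **Fib** — alphabet {0, 1}, rules 0 → 1, 1 → 01. Generation lengths follow
  the Fibonacci numbers; from the axiom `"0"`, generation 12 has 233 symbols.
* **Skip** — rules 0 → 01, 1 → 01101. Each symbol rewrites as a
  non-subsequent Fib generation, which preserves the surface laws but
  destroys the recurrence between adjacent generations.

Both languages obey the **Three Laws**: a 0 is always followed by a 1
(`00` never occurs), two 1s are always followed by a 0 (`111` never occurs),
and a single 1 may be followed by either symbol — the only locally ambiguous
context.

## k-points and why Skip has none

In the Fib derivation tree, a **k-point** is a 1 immediately dominated by a
0 that immediately dominates the constituent [0 1]. A k-point labels its
whole neighbourhood: its parent must be a 0, its children must be 0 1, and
successive k-points are always 3 or 5 symbols apart, with succession rules
(3 → 5; 5 → 3 or 5; 5,5 → 3) that mirror the Three Laws one level up —
the grammar's self-similarity. Knowing only a string's length and its
k-positions is enough to rebuild it (`reconstruct_from_skeleton()`).

At the string level the same points fall out of a purely statistical
operation: chunk the string greedily into [01] bigrams (the unit the First
Law makes fully predictable) and the stranded 1s that cannot start a chunk
are exactly the k-points. `classify_points()` implements the tree
definition, `k_positions_by_segmentation()` the string definition, and the
test suite asserts their equivalence on Fib generations 2–20.

Skip strings *also* produce stranded 1s under segmentation — but none of
them is a k-point: a Skip 1 rewrites as the 5-symbol block 01101, so the
downward dominance clause fails everywhere, and the stranded-1 gaps
(5 and 7 in generation 4) never follow the forced Fib gap pattern. That
dissociation — same surface laws, same ambiguous trigram 011, no structure
behind it — is what the whole design leans on.

Two conventions are worth making explicit because the derivations force
them rather than any source stating them:

* **Axiom and indexing.** The axiom is the single symbol `"0"` and counts as
  generation 0. This is the unique convention under which Fib generation 12
  has 233 symbols, generations 10 and 9 have 89 and 55 (the experimental
  block sizes), and Skip generation 4 has 97.
* **Final-generation classification.** The k test needs a position's
  children; for the last materialized generation `classify_points()` uses a
  one-step lookahead rewrite. Without it the final generation — the one the
  experiment presents — would be unclassifiable.
* **Reconstruction refuses to guess.** Only forced slots are filled: a
  prefix of 0 or 2 slots before the first k, the [01] after every k, the
  two slots closing a 5-gap, and at most two trailing slots. Anything else
  raises an error rather than returning one of several consistent strings.

## The task

`build_trials()` assembles the 330-trial modified Simon task: Fib
generation 12 split contiguously into blocks of 89, 89 and 55 trials, then
Skip generation 4 (97 trials) as block 4, presented without interruption.
Symbol 0 is a red square answered with key 1 (left); symbol 1 is a blue
square answered with key 0 (right). Congruent trials show the square on its
key's side; every sixth trial is incongruent (opposite side). The phase of
that schedule is anchored at trial 6 and sides are fully determined by
congruency — the design ties side to congruency and nothing else, so no
extra randomization is introduced.

Three context flags mark the analysis targets, read across block
boundaries: `a1` (blue after red — First-Law continuations), `a2` (red
after two blues — Second-Law continuations) and `a3` (blue after red–blue —
the 011 trigram whose final 1 is a k-point in Fib and a plain 1 in Skip).
In the default table all 55 Fib `a3` targets are k-points and the Skip
block contributes 15 non-structural ones.

## The simulated cohort

No per-child data ship with the package, so `simulate_cohort()` generates a
cohort with the statistical structure the analyses assume: 22 subjects,
330 trials each. Three nested learner models dissociate the analyses:

* **static** — expectancy pinned at 0.5; no sequence information reaches
  the RTs. Used as the negative control.
* **sequential** — one expectancy trace per left context (after-0,
  after-single-1, after-11, start) and symbol, updated exponentially:
  `new = (1 − rate) · old + rate · observed`. Traces start at 0 ("no
  expectancy") and converge to the empirical transition frequencies, so
  after N confirmations a trace sits at `1 − (1 − rate)^N`. Starting at 0
  rather than 0.5 makes the traces leaky evidence counters that sum to 1
  only asymptotically; it keeps the chance-level state the exclusive
  property of the static learner and gives the clean closed form above.
* **structural** — the sequential learner plus a k-tracker that switches on
  once the after-0 expectancy exceeds `first_law_threshold` (default 0.8):
  acquiring the First Law is what licenses segmentation. The tracker notes
  stranded 1s online and projects the next k-position whenever the gap
  pattern forces it (after a 3-gap, and after a 5,5 pair). On Fib these
  projections are always correct; on Skip the forcing patterns never occur
  and the tracker stays silent. Projected slots earn the `k_gain` benefit.

Reaction times follow a censored log-normal model. For trial *t* of subject
*s*:

    mu = intercept_s · (1 − practice_decay · t/100)
         + congruency_penalty · [incongruent]
         − anticipation_gain · P̂(shown symbol)
         − k_gain · [projected k-slot]
    RT  = exp(log mu + ε),   ε ~ N(0, noise_sd)

with `intercept_s ~ N(base_mean, subject_sd)`. Draws above the 1000 ms
deadline become timeouts, are scored incorrect, and never enter RT means;
other trials are correct with the per-condition accuracy probability.
The log-normal choice gives strictly positive, right-skewed RTs — the
standard assumption for this kind of data.

### Defaults and how they were chosen

| parameter | default | role |
|---|---|---|
| `learning_rate` | 0.05 | spreads First-Law acquisition over block 1 |
| `anticipation_gain` | 110 ms | block-1 → block-3 RT decrease at forced positions |
| `k_gain` | 80 ms | Fib-vs-Skip difference at a3 targets |
| `first_law_threshold` | 0.8 | k-tracking opens near the end of block 1 |
| `base_mean` / `subject_sd` | 549 / 80 ms | block-1 congruent cell ≈ 504 ms |
| `congruency_penalty` | 230 ms | block-1 incongruent cell ≈ 699 ms after censoring |
| `noise_sd` | 0.22 (log scale) | trial-level variability and timeout rate |
| `practice_decay` | 0 | see below |
| `accuracy` | .96 / .71 | overall proportion correct ≈ 0.91 |

The defaults were calibrated once, against three fixed anchors: the
study-level block-1 First-Law cell means (≈ 504 ms congruent, ≈ 699 ms
incongruent), the 91% overall proportion correct, and the power targets of
the design — a structural-learner cohort should show a significant
Analysis-3 grammar effect in at least 80 of 100 replicates while a
sequential-learner cohort (identical except `k_gain = 0`) does so in at
most 10. Under the defaults the measured rates are 89/100 and 5/100.

`practice_decay` defaults to 0 deliberately: the static learner is the
negative control for Analysis 1, and any nonzero motor-practice decay would
hand it a spurious Block effect by construction. All block-level RT
decrease in the simulated data therefore comes from the learning model.

### What the generator does and does not emulate

It reproduces the design's cell structure (counts of targets per
congruency, block and grammar, including the sparse Skip incongruent a3
cell of 2 trials, which occasionally empties and triggers the same listwise
subject loss the original analysis shows), the censoring regime, and
between-subject intercept spread. It does **not** model per-child
covariates, response conflict dynamics, fatigue, or any asymmetry between
congruent and incongruent structural benefits: the congruency penalty is
additive, so the simulated Fib-vs-Skip difference is roughly equal in the
two congruency conditions (≈ 45–55 ms), whereas the original report shows
a larger incongruent than congruent difference. Passing calibration checks
therefore says the generator matches the study's headline anchors, not that
it is a faithful process model of children's responses.

## The analyses

`run_analysis()` reproduces the three analyses: per-subject mean RTs over
correct, non-timeout target trials feed a two-factor within-subject ANOVA
(congruency × block for Analyses 1–2; congruency × grammar for Analysis 3,
with the three Fib blocks pooled because the per-block incongruent k cells
are tiny). Effects are tested against their own effect-by-subject error
strata; effect size is partial η² = SS_effect / (SS_effect + SS_error).
Block analyses add Bonferroni-corrected paired comparisons of the block
marginal means, with the multiplier m = L(L−1)/2 = 6; marginals are taken
over congruency at the subject level. Accuracy is reported descriptively
only — with near-ceiling congruent accuracy the RT analyses carry the
information.

Numerical and design choices:

* The decomposition is fitted with `stats::aov()` and an
  `Error(subject/(A*B))` stratification; the test suite checks it against
  an independently coded mean-deviation decomposition to 1e-9 relative
  tolerance on 50 random balanced designs, and checks that the seven
  components reassemble the total sum of squares.
* No sphericity correction is applied by default; congruency and grammar
  have two levels each, where the question cannot arise, and the block
  factor follows the uncorrected degrees of freedom the analyses report.
* A subject with an empty cell (no correct trials) is dropped listwise with
  a warning naming the subject and cell; `condition_means()` can be made to
  error instead. This mirrors the unexplained reduction to F(1, 19) in the
  original grammar analysis.
* Zero-variance pairwise comparisons are defined: all-zero differences give
  t = 0, p = 1; a constant non-zero difference is reported with its mean
  and an undefined t rather than an infinite one.
* Effects with zero sum of squares report F = 0, p = 1, partial η² = 0
  rather than 0/0.

## Problem sizes and reproducibility

Derivation properties are asserted up to Fib generation 20 (10,946 symbols)
and Skip generation 6; derivations are capped at 30 generations to bound
memory. Stochastic properties use 100 replicates of 22 × 330-trial cohorts,
which keeps the whole test suite under a minute on one CPU. Every source of
randomness flows from a single master seed; subjects get substreams via a
fixed prime offset, so cohorts are byte-reproducible and
`reproduce_study()` re-creates identical CSVs from the same seed.

## Known limitations

* The learner family is the minimal set that dissociates the three
  analyses, not a fitted cognitive model; its parameters are design
  calibrations, not estimates.
* The additive congruency penalty cannot reproduce a congruency ×
  structure interaction (see above).
* Whether the published 91.07% accuracy counts timeouts in its denominator
  is not documented; the generator counts them as errors, and the
  calibration tolerance absorbs the difference.
* The gap-succession validator checks the three forcing rules only; a gap
  value outside {3, 5} in first position is not itself flagged (no rule
  constrains it), though skeleton reconstruction rejects it.
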