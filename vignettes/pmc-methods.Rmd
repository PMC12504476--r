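---
title: "The PMC index model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PMC index model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcindex)
```

## The model and its assumptions

The Policy Modeling Consistency (PMC) index scores a policy text against a
fixed indicator system. A schema defines P primary variables (policy
dimensions); primary *i* holds *n_i* binary secondary variables, each a
yes/no criterion judged against the text. The model's central assumption is
**equal weighting at both levels**: every secondary variable under a primary
counts the same (the score of primary *i* is the plain mean of its bits),
and every primary counts the same in the index (the index is the plain sum).
This is deliberate — the model measures internal consistency and coverage of
a policy, not expert-weighted importance — and the package provides no
alternative weighting.

Scoring itself is human content analysis: a researcher reads the policy and
records 1 where the text meets a criterion. The package records, validates,
and aggregates those judgments; it does not attempt to automate them. Some
model write-ups express the binary assignment in distribution-like notation
(an "N[0,1]" over {0,1}); the procedure is plainly deterministic binary
assignment and is implemented as such.

With the bundled 9×33 schema the index ranges over [0, 9] and is graded
*Weak applicability* (≤ 6.50), *Focused* (6.50, 7.50], or *Reasonable and
Complete* (> 7.50). The breakpoints are conventions of the PMC literature,
not fitted quantities; `pmc_grade_scale()` accepts any strictly increasing
set.

## Rounding: the load-bearing detail

Published PMC tables report two decimals, and they are reproducible **only**
if each primary score is rounded before the nine are summed: the bundled
table contains policies whose exact-fraction index (e.g. 1 + 1 + 2/3 + 2/3 +
3/5 + 1 + 1 + 4/5 + 3/4 = 7.4833) differs in the second decimal from the
round-then-sum value (7.49). The package therefore defaults to
`mode = "rounded2"` — round half-up to two decimals at the primary-score
level, then sum, classify, rank, average, and order gaps on those reported
values — and offers `mode = "exact"` for principled unrounded use. The two
modes disagree on three of the ten bundled policies, which the test suite
pins as the discriminating cases.

Half-up (2/3 → 0.67) rather than R's default round-half-to-even is used
everywhere a reported value is produced; `round_half_up()` documents the
arithmetic, including the 1e-9 guard against binary floating point
representing `(2/3)*100` fractionally below 66.67.

Improvement-path gaps are computed on the two-decimal scores against the
two-decimal cross-policy means, consistent with the reported tables. Ties in
gap are broken by ascending primary index. This tie rule is a package
convention: published orderings of equal-gap variables are not internally
consistent, so no rule can match them all, and a documented deterministic
choice is preferable to guessing. Tests assert only paths that the gap
ordering determines (up to the ascending-index rule).

## Parameters that matter

- **`mode`** (`"rounded2"`/`"exact"`): see above. Default `"rounded2"`.
- **Grade scale**: breakpoints 6.50/7.50 with the three standard labels;
  classification applies left-open/right-closed intervals to the two-decimal
  reported index, so 7.50 is *Focused* and 7.51 is not.
- **Ranking ties**: stable by input order. No ties occur in the bundled
  table.
- **Surface upsampling `factor`** (default 20 in plots): purely cosmetic
  refinement of the 3×3 grid. Bilinear interpolation is the default because
  it is a convex combination of the four surrounding cells, so the rendered
  surface is provably clamped to the score range; bicubic-style overshoot
  would invent depressions that the data does not contain.
- **Concavity**: the literature reads surface concavity visually. The
  package quantifies it as `1 − score` per cell (total depression
  `9 − Σ scores`), a documented extension chosen for its direct
  interpretation as shortfall from a full score.
- **Co-occurrence unit**: one line (sentence) of the tokenized corpus.
  Window-based co-occurrence can be emulated by re-unitizing upstream; the
  unit definition is the single knob that changes the network.
- **`top_n`** network nodes (default 50), frequency ties broken
  lexicographically so node sets are deterministic.

## The synthetic generators

`simulate_score_table()` draws every (policy, secondary) bit as an
independent Bernoulli variable — scalar, per-primary, or per-secondary
probabilities — under a fixed Mersenne-Twister seed, restoring the caller's
RNG state. It emulates the *shape* of a real multi-input–output table, not
its dependence structure: real tables show strongly correlated criteria
(several bundled criteria are met by all ten policies), and no generative
model of that dependence is attempted. Consequently, passing tests on
synthetic tables demonstrates arithmetic correctness (bounds, monotonicity,
parameter recovery) — not that any distributional claim holds for real
policy corpora.

`simulate_corpus()` plants hub terms into every unit, so each hub co-occurs
with every other kept term wherever that term appears; hub dominance of
weighted degree is then a ground truth by construction, which the network
tests exploit. Test problem sizes (500 synthetic policies for parameter
recovery, a few dozen units for network properties) keep the whole suite in
seconds while leaving Monte Carlo margins of three standard errors.

## Numerical and degenerate-input choices

- Validation collects *all* violations (duplicate ids, malformed id
  patterns, empty primaries, non-binary or missing cells) before aborting,
  with a dedicated condition class (`pmcindex_validation_error`) so callers
  and the CLI can distinguish validation failures (exit 1) from I/O errors
  (exit 2).
- Empty score tables are valid objects; evaluating one is an error.
  A zero-policy write produces a header-only document that reads back.
- The compact dialect mirrors the transposed printed layout of such tables
  (rows = primaries, columns = policies, cells = bitstrings); bit order
  within a cell follows the schema's secondary order, and lengths are
  checked against each primary's secondary count.
- Reporting computes everything before writing anything, so a failed
  validation leaves no partial outputs; reruns overwrite byte-identical
  tabular files.

## Known limitations

- No automated scoring of raw policy text against criteria; the binary
  judgments are inputs.
- Chinese word segmentation is out of scope: the corpus reader expects
  pre-segmented text (whitespace tokens) and accepts a pluggable tokenizer.
- The co-occurrence network reports weighted degree; layout-dependent
  notions of centrality ("closeness to the network center") are not
  computed.
- The equal-weight model is taken as given; no sensitivity analysis over
  weights or grade breakpoints is provided.
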