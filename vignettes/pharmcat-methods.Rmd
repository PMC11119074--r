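---
title: "Scoring pharmacy workload complexity in sponsored trials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pharmacy workload complexity in sponsored trials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmcat)
```

## The problem

Investigational drug services at cancer research centres carry a workload
that varies enormously from trial to trial: a phase III study with a single
ready-to-use oral drug is a different commitment from a blinded phase I
study with deep-freeze storage, manual resupply and personalised dose
preparation. When pharmacy grants are negotiated at the contracting stage,
a trial's complexity *from the pharmacy's point of view* needs to be
assessed before the trial starts, from protocol information alone.

`pharmcat` implements a 15-item complexity assessment instrument for
sponsored oncology and haematology trials as a reusable scoring engine:
item-level scoring, tertile-based category cut-offs, ordinal
categorisation, inter-rater reproducibility statistics, stratified cohort
summaries, and a synthetic cohort generator for end-to-end testing.

## The instrument

The default instrument has 15 items in three sections — study design
(items 1–5), drug management (6–11) and drug preparation (12–15). Each
item offers a small set of allowed score levels between 0 and 3 points;
most items are scored 1/2/3, several binary items are scored 1/3 or 2/3,
and two drug-preparation items include a 0-point "not applicable" level.
A trial's total is the plain sum of its 15 item scores, giving an
achievable range of 15–44 points:

```{r}
inst <- default_instrument()
score_bounds(inst)
```

Item 1 (study phase) is special: it scores 3 points for a phase I trial
and 1 point otherwise, so it is fully determined by an objective trial
property. Validation therefore treats a phase/item-1 mismatch as a
recording error by default (`check_phase = TRUE` in
`validate_assessments()`); the check can be relaxed for instruments in
which item 1 has been repurposed.

The instrument is *data*, not code: `default_instrument()` loads a
packaged JSON config, and `load_instrument()` accepts a modified config —
items added, dropped or rescored for a particular pharmacy service —
without any code change. All invariants (unique item ids, at least two
distinct levels per item, scores in 0–3) are enforced at load time.

`achievable_totals()` computes the exact set of reachable totals by
dynamic programming over items (folding each item's level set into the
set of partial sums). The test suite checks this against exhaustive
enumeration of all 559,872 level combinations of the default instrument.

## Category cut-offs from tertiles

Totals are mapped to ordinal complexity categories (low < medium < high)
using two inclusive upper bounds. Cut-offs are derived empirically from a
development cohort's score distribution at the first and third tertiles.
The tertile rule needs a precise convention for integer scores with
ties; `derive_cutoffs()` uses order statistics: with the $n$ scores
sorted ascending, the low/medium boundary is
$s_{(\lceil n/3 \rceil)}$ and the medium/high boundary is
$s_{(\lceil 2n/3 \rceil)}$, each an inclusive upper bound. This choice
is deterministic under ties, always returns boundaries that are observed
scores, and guarantees at least a third of the cohort falls in the low
category. When the two boundaries coincide the distribution is too
concentrated to support three categories and the function raises a
degenerate-distribution error rather than silently collapsing categories.

The reference cut-offs established on the original development cohort
(low ≤ 19, medium 20–25, high ≥ 26) are packaged as `study_cutoffs()`;
they are a published constant, not something this package re-derives.
Note the low category accepts any total from 0 even though the default
instrument cannot score below 15 — totals below the instrument minimum
are a validation concern, not a categorisation concern.

```{r}
categorize(c(19, 20, 25, 26), study_cutoffs())
```

## Inter-rater reproducibility

The study design has every trial scored independently by two pharmacists.
`agreement_report()` assembles:

* **exact-score concordance** — the share of trials with identical totals,
* the **absolute score-difference histogram** and its mean,
* the **3×3 cross-classification** of rater A's vs rater B's category,
* the number of trials placed in the **same category** by both raters,
* **Cohen's linear weighted kappa** on the cross-classification.

Kappa uses linear disagreement weights $w_{ij} = |i-j|/(k-1)$ and the
form $\kappa_w = 1 - \sum w_{ij} p_{ij} / \sum w_{ij} e_{ij}$, with
$e_{ij}$ the chance-expected proportions from the margins. This is
algebraically identical to the agreement-weight form
$(p_o - p_e)/(1 - p_e)$, which the test suite uses as an independent
oracle. Kappa is computed on the three complexity categories by default,
because the categories are the instrument's operational output once
cut-offs are established; `kappa_on = "total"` treats every observed
total as its own ordinal level instead, as a sensitivity analysis. When
both raters put every trial in one category the chance-disagreement
denominator vanishes; the report then flags perfect-but-degenerate
agreement (`perfect_agreement = TRUE`) instead of returning a number.

Exactly two raters per trial are supported — that is the reproducibility
design — and the pairing takes rater A to be the first-listed rater of
each trial. Summary statistics are kept at full precision and rounded
half-away-from-zero to two decimals only for display (`round_half_up()`),
with exact-agreement additionally shown at zero decimals.

## The synthetic cohort generator

The original assessment data are confidential, so the generator
(`generate_cohort()`) produces cohorts with the development study's
structure for testing every downstream module. The default configuration
(`default_study_config()`) fixes the study's composition: 60 trials,
split 40/20 between two centres, 39 oncology / 21 haematology, and
6/18/36 trials in phases I/II/III, allocated as exact counts
(largest-remainder rounding) and shuffled.

Rater A's responses are drawn from per-item categorical distributions
over the allowed levels. The real per-item response frequencies are
unknown; the packaged model (`default_item_model()`) was chosen once to
reflect a plausible sponsored oncology/haematology portfolio — mostly
injectable drugs, frequent IWRS involvement, blinding in a minority of
trials, rare personalised administration — and calibrated so the expected
cohort mean total is about 22.9 points with totals concentrated between
the high teens and low thirties. Item 1 is set deterministically from
the trial's phase for both raters and is never perturbed, since phase is
objective.

Rater disagreement is modelled at *item* level, not by adding noise to
totals, so generated data exercise the validation and scoring paths:
rater B starts from rater A's form and each non-phase item independently
moves to an adjacent allowed level with probability $p$ (direction
uniform when two neighbours exist). Because every perturbation lands on
a different allowed score, a pair's totals can only coincide exactly when
no item was perturbed or when perturbations cancel; ignoring the rare
cancellations, the expected exact-agreement fraction has the closed form
$(1-p)^{m}$, where $m = 14$ is the number of perturbable items
(`expected_exact_agreement()`). The default
$p = 1 - 0.77^{1/14} \approx 0.0185$ solves $(1-p)^{14} = 0.77$, matching
the 77% exact agreement observed in the development study. Adjacent-level
moves on items whose levels are 2 or 3 points apart also reproduce the
occasional 2- and 4-point total discrepancies seen in practice.

Random draws are consumed in a fixed order independent of $p$, so cohorts
generated from one seed at different $p$ values share common random
numbers: raising $p$ only adds perturbed cells. Response-level agreement
is therefore non-increasing in $p$ seed by seed, and total-level
agreement in expectation. A seed is mandatory — there is no silent global
randomness.

What the generator does *not* emulate: correlations between items (e.g.
blinded trials tending to involve IWRS treatment assignment),
phase-dependent response distributions beyond item 1, centre effects, and
systematic rater bias (perturbations are symmetric). Passing tests on
synthetic cohorts therefore demonstrate the correctness of the scoring,
categorisation and agreement machinery under the study's design, not the
field performance of the instrument itself.

## Reporting conventions

`summarize_cohort()` produces the stratified results table: a total row,
then per-centre, per-type and per-phase rows, each with trial counts,
percentage of cohort, mean total, and within-stratum category counts and
percentages. Two reporting ambiguities are exposed as explicit options
rather than resolved silently:

* **Collapsing two raters to one trial** (`per_trial_rule`): the default
  `"rater_a"` uses the first-listed rater's total; `"mean_floor"` (floor
  of the pair mean) and `"max"` are provided as alternatives. The
  pair-based rules require exactly two raters per trial and fail
  otherwise.
* **Unit of analysis** (`mode`): `"per_trial"` (default) summarises each
  trial once after collapsing; `"per_score"` summarises every recorded
  score, for cohorts whose reported mean is taken over all scores rather
  than over trials.

Percentages are rounded half-away-from-zero to two decimals (so 19/60
prints as 31.67), matching how such tables are conventionally formatted.

## Numerical and testing choices

* All scores and totals are integers end to end; no floating-point
  comparisons enter scoring or categorisation.
* Kappa equality against the independent oracle is asserted to
  $10^{-12}$ on 1,000 random 3×3 tables.
* Property suites run at sizes chosen to keep the default test run
  fast while still exercising the space thoroughly: exhaustive
  enumeration of all 559,872 default-instrument combinations once, 100
  random small instruments for the dynamic program, 100–200 seeds for
  generator properties, and a four-point $p$ grid for the monotonicity
  check.
* Errors are classed conditions (`pharmcat_schema_error`,
  `pharmcat_validation_error`, `pharmcat_insufficient_data`,
  `pharmcat_degenerate_distribution`, `pharmcat_undefined_kappa`,
  `pharmcat_parse_error`, `pharmcat_data_error`, `pharmcat_domain_error`)
  so callers can distinguish data problems from bugs; validation
  *violations* within an otherwise well-formed table are returned as
  data, not raised.

## Known limitations

* The instrument's scientific validity (do the items capture pharmacy
  workload? are the weights right?) is outside what software tests can
  establish; the package implements the instrument, it does not validate
  it.
* The packaged reference cut-offs come from a single two-centre
  development cohort; multicentre validation may revise them. The
  config-driven design anticipates this: derive new cut-offs with
  `derive_cutoffs()` and pass them everywhere cut-offs are accepted.
* Only two raters per trial are supported, matching the reproducibility
  design; generalised multi-rater agreement is out of scope.
* No confidence intervals for kappa are computed.
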