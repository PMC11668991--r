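---
title: "Methods: evaluating EMA data quality with emaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating EMA data quality with emaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaqc)
```

## The problem

Intensive longitudinal (EMA / experience-sampling) studies deliver brief
surveys several times a day in participants' natural settings. Their
scientific value hinges on data quality along four axes that this package
quantifies in one pipeline: **participation** (who of the invitees provided
any data), **compliance** (what share of scheduled prompts each participant
answered, and how that decays over days), **reliability** (whether the
momentary scales distinguish persons, and changes within persons, better than
noise), and **careless responding** (answers given without attention, which
inflate apparent compliance while degrading every downstream estimate).

The reference design is 14 EMA days with 4 prompts/day delivered at a random
moment inside fixed 2-hour windows (08, 12, 16, 20 h), a 30-minute reminder,
expiry at the end of the window, and a maximum of 56 assessments per person.
Every prompt carries 12 seven-point Likert items: momentary stress, energy,
concentration, 5 positive-affect (PA) items and 4 negative-affect (NA) items.
PA and NA scores are the per-assessment means of their items; the scales are
unipolar and nothing is reverse-coded.

## Models and estimators

### Participation and compliance

Participation rate is `n_participated / n_invited`, where participating means
completing at least one momentary assessment. Compliance is
`n_completed / 56` per person, deliberately never pro-rated by enrollment
date. Predictor models follow standard epidemiological practice: one exposure
at a time, always adjusted for the four sociodemographic/college covariates
(reference categories: male, Spanish, 18–21, arts & humanities),

* participation: logistic regression, odds ratios with Wald 95% CIs;
* compliance: Poisson regression of the completed count with an offset of
  log(56), exponentiated coefficients (rate ratios) with Wald CIs.

Whether the count model uses an offset or models the proportion is
observationally equivalent when every denominator is 56; the offset
formulation is implemented because it generalizes to designs with varying
denominators. Counts out of 56 are not Poisson (they are bounded and
typically under/over-dispersed), so a robust HC0 sandwich variance is exposed
as an option (`robust = TRUE`); the plain-Poisson Wald interval remains the
default for fidelity with common reporting practice. Complete separation or
empty cells are reported as non-estimable terms with a diagnostic note rather
than an error.

### Variance decomposition and ICC

`decompose_two_level()` fits `score ~ 1 + (1 | person)` by REML (lme4), which
handles the unbalanced occasion counts that missingness produces. For
balanced data the estimates coincide with the one-way expected-mean-squares
(EMS) solution σ̂²_B = (MSB − MSW)/n, σ̂²_W = MSW; the test suite asserts
agreement to 1e-6 on balanced fixtures and the degenerate limits (all scores
constant → both components 0; persons constant at distinct levels → ICC 1).
The ICC is σ²_B/(σ²_B + σ²_W); values below 0.5 mean the score varies mostly
within persons, which is precisely what justifies momentary measurement.

### Multilevel reliability

`decompose_three_level()` fits the crossed-within design
`response ~ 1 + (1|person) + (1|person:occasion) + (1|item) + (1|person:item)`
by REML, giving five components: person σ²_P, time-within-person σ²_T(P),
item σ²_I, person×item σ²_P×I, residual σ²_ε. A pure nesting of items inside
assessments would leave no person×item term, but the between-person
generalizability coefficient requires σ²_P×I, so the crossed-within
formulation is used (the five-way EMS method-of-moments solution on balanced
fixtures is the independent oracle, agreement ≤ 1e-4). REML truncates
negative components at zero by construction; components at the boundary are
listed in a diagnostic field.

`multilevel_reliability()` evaluates the Shrout–Lane coefficients:

* between-person reliability of k-item scores averaged over n time points,
  R_kRn = (σ²_P + σ²_P×I/k) / (σ²_P + σ²_P×I/k + σ²_T(P)/n + σ²_ε/(k·n));
* within-person (change) reliability, R_cn = σ²_T(P) / (σ²_T(P) + σ²_ε/k).

When occasion counts vary across persons, n is the harmonic mean of the
per-person counts — the standard generalizability-theory choice for
unbalanced designs, reducing to the common n when balanced. Both coefficients
are clamped to [0,1] and labelled by the classic bands (0.00–0.10 practically
none, 0.11–0.40 slight, 0.41–0.60 fair, 0.61–0.80 moderate, 0.81–1.00
substantial; applied after rounding to 2 decimals). Per-person raw Cronbach α
(`person_alpha()`) uses the variance form α = k/(k−1)(1 − Σs²ᵢ/s²_total)
across one person's occasions; it is missing with fewer than two occasions or
when the occasion sums never vary (no-variation participants have no α), and
may legitimately be negative.

### Careless responses and responders

Three per-assessment parameters: time per item (duration divided by the item
count *of that record* — morning/evening assessments carry more items),
sample SD of the 12 common responses, and percent-at-mode. The response-level
rule flags a completed assessment when time per item ≤ 1 s or SD = 0. The 1 s
boundary is inclusive (the operational description uses ≤) and configurable.
Psychometric antonyms are selected as the item pair with the most negative
full-sample Pearson correlation (ties broken toward the lowest item indexes,
constant items excluded, a warning when nothing negative exists), and
`antonym_threshold_curve()` traces the antonym correlation in the suspicious
tail of each parameter (≤ threshold for time and SD, ≥ for percent-at-mode).
In a straight-lined subset both antonym values are equal within every
assessment, so the curve hits r = 1 exactly whenever the subset varies across
assessments — a useful built-in sanity limit.

Responder-level rules: `minimum_valid_assessments()` takes every person with
≥ 40 completed assessments, uses their first 40 in chronological order as the
gold standard (a deterministic choice; the alternative — a seeded random 40 —
is a config knob away and was judged less reproducible), draws 5 random
subsets per size s ∈ 2..40, computes each person's subset mean and SD of PA
and NA, and averages the two-way single-rater absolute-agreement ICC against
the gold standard over the 5 replicates *before* thresholding. "Stabilized"
is operationalized as: the smallest s from which all four averaged curves
stay ≥ 0.90 at s and at every larger evaluated size. A person is a potential
careless responder when their valid (completed minus careless) assessments
fall below that minimum, or when raw α < 0.11 on either scale (negative α
counts; a missing α is reported but does not trigger the rule by itself).
Flags mark, never drop.

## The synthetic cohort generator

The generator states one world and stays there; none of its defaults were
tuned against test outcomes.

* **Design**: 780 participants, subsample shares 21.4/29.9/26.3/22.4%
  (suicidal ideation / alcohol / anxiety-depression / control), covariate
  distributions matching the invited sample of the reference study.
* **Compliance**: person-level completion probabilities are Beta with mean
  0.769 and SD 0.277, plus a centred linear day trend of −0.005/day (the
  reference study reports a gradual linear decline but no slope; −0.005 gives
  a realistic ≈ 6.5-point drop over 13 days). Missingness is completion-only:
  an assessment is wholly completed or wholly missed.
* **Affect**: latent PA and NA are person intercept + momentary deviation
  around the scale midpoint 4, with between/within variances 0.94/0.81 (PA)
  and 0.88/0.80 (NA) and a latent PA–NA correlation of −0.5 (typical of
  momentary affect; unstated in the source, chosen once) so that psychometric
  antonyms exist by construction. Momentary deviations are exchangeable by
  default; an optional AR(1) knob (`ar1_affect`) induces autocorrelation at
  unchanged stationary variance.
* **Items**: each item is its scale latent plus item (σ²=0.05), person×item
  (σ²=0.10) and residual (σ²=3.0) noise, rounded and clamped to 1..7. The
  residual value was chosen so that within-person reliability lands in the
  fair-to-moderate range (R_cn ≈ 0.5–0.6 at k = 4–5) while between-person
  reliability stays near 1 — the qualitative pattern real momentary affect
  data show. The stress/energy/concentration items load on the NA latent.
* **Timing**: prompt-to-start latency lognormal with median 15 min (sdlog
  0.9), time per item lognormal with median 3.9 s and sdlog 0.35 — at that
  spread an honest assessment crosses the 1 s flag at rate ≈ 5e-5, honouring
  the design requirement of a near-zero false-positive rate at defaults.
  Completed assessments always end before window expiry.
* **Careless injection**: 0.13% of completed assessments become fast
  (time/item uniform on 0.2–0.95 s) and 0.78% straight-lined (all 12 items
  set to one of the assessment's own values), assigned first to a designated
  cluster of 8 participants until their assessments are exhausted, then
  uniformly — reproducing the empirical clustering of careless behaviour in
  a minority of participants.

### What the generator does *not* emulate

Likert rounding and clamping shrink the between-person variance and the item
noise inflates the within-person variance of the *discretized* scores, so the
ICC of the generated 1–7 scores sits visibly below the latent 0.54/0.52 —
recovery tests therefore target the continuous latents (carried in the truth
table) or use `simulate_two_level_scores()`, which generates continuous
scores directly. The generator has no item-level missingness, no day-1/15
questionnaires, no add-on item content (only the item *counts* of
morning/evening records), no refusal stage (participation is near 1 minus the
chance of completing zero prompts), and no relationship between covariates
and compliance — so a green pipeline run establishes the estimators' and
rules' correctness, not any epidemiological claim about predictors.

## Numerical choices and edge cases

* Sample SD (n−1) for the 12-item dispersion; the flagging rule only uses
  SD = 0, which is convention-free, and threshold curves are monotone in
  either convention.
* ICCs and reliabilities are reported to 2 decimals, percentages to 1; full
  precision is kept internally.
* Threshold-curve subsets with < 3 assessments or a constant antonym item
  return a missing correlation, never an error; empty model strata return
  non-estimable rows.
* `stability_icc()` is deliberately not clamped: near-zero between-person
  variance produces values ≤ 0, which is itself diagnostic.
* All randomness flows from one integer seed; sub-streams (cohort, schedule,
  responses, stability subsampling) use fixed offsets from it, so every
  artifact is byte-reproducible under a fixed configuration.

## Known limitations

Plain Poisson intervals for bounded counts are anti-conservative under
overdispersion (use `robust = TRUE` for sensitivity); the three-level model
assumes the crossed-within structure stated above rather than estimating
alternative nestings; the stability procedure inherits the arbitrariness of
the 40-assessment gold standard (participants below 40 completed assessments
are simply outside that analysis); and the careless rules are post hoc
screens, not ground truth — on real data their sensitivity cannot be
measured, which is exactly why the generator carries an injected-truth table.
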