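---
title: "Counterfactual mediation by G-computation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual mediation by G-computation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

`gcompmed` estimates how much of the effect of perceiving nurses as
helpful (a binary exposure X, "always" vs less often) on exclusive
breastfeeding in the first days postpartum (a binary outcome Y) runs
through breastfeeding self-efficacy (the mediator M, the BSES-SF sum
score on 14–70, typically analysed as a high/low split at 56). The
estimand set is the standard counterfactual decomposition on the
risk-difference scale:

* **TCE** (total causal effect): `E[Y(1, M(1))] − E[Y(0, M(0))]` — the
  average treatment effect of the exposure.
* **NDE** (natural direct effect): `E[Y(1, M(0))] − E[Y(0, M(0))]` —
  the exposure's effect with the mediator held at the level it would
  take without exposure.
* **NIE** (natural indirect effect): `TCE − NDE`, the mediated
  portion; the proportion mediated is `NIE / TCE` when the total
  effect is non-null.

These three quantities are built from three counterfactual means
(`mu_11`, `mu_00`, `mu_10`), each estimated by the parametric
g-formula: fit one equation for the mediator and one for the outcome,
then standardise model predictions over the observed confounder
distribution under the hypothetical exposure assignments.

## Model and algorithm

Two regression equations are fitted on minimal sufficient adjustment
sets:

* **M-equation** — linear least squares. For the binary high/low
  mediator this is a linear probability model (the default,
  `m_binary_family = "linear_probability"`), with a logistic option;
  for the raw score it is an ordinary gaussian linear model.
* **Y-equation** — logistic regression on exposure, mediator and the
  outcome-equation adjustment set.

For a counterfactual mean `E[Y(x, M(x'))]`, every record's mediator is
simulated `mc_draws` times from the fitted M-equation with the
exposure column overridden to `x'` (gaussian: linear predictor plus
normal residual noise; linear probability: Bernoulli with the
predictor clipped into `[1e-6, 1 − 1e-6]`, clips counted and
reported; binomial: Bernoulli(expit)). The outcome probability at
`(x, m, C)` is then evaluated from the fitted Y-equation and averaged
over records and draws.

**Analytic outcome averaging.** The outcome's expectation given
`(x, m, C)` is known exactly from the fitted logistic curve, so the
default averages predicted probabilities rather than drawing Bernoulli
outcomes. Both have the same expectation; averaging removes one layer
of Monte Carlo noise. A `draw_y = TRUE` mode draws the outcomes
instead, for fidelity checks against the fully simulated variant.

**Identification assumptions.** No unmeasured exposure–outcome,
exposure–mediator, or mediator–outcome confounding given the selected
adjustment sets; no mediator–outcome confounder caused by the
exposure; correctly specified equations; consistency and positivity.
The package checks none of these against reality — they are encoded in
the user's DAG.

## Adjustment-set selection

The causal DAG is supplied as a plain-text edge list with role lines.
d-separation is decided by reachability in the moralised ancestral
graph, and minimal sufficient adjustment sets by exhaustive search
over subsets of eligible nodes (observed, not the roles, not
descendants of the exposure) in order of increasing size, keeping sets
with no sufficient proper subset. Graphs in this setting have fewer
than 15 nodes, so exact enumeration is cheap and preferred over
heuristics; both algorithms are validated in the test suite against
independent brute-force oracles (path enumeration; subset search).

For the mediator equation, the mediator is treated as a temporary
outcome and the backdoor criterion applied to the exposure–mediator
pair. For the outcome equation, which conditions on both exposure and
mediator, a set must block the exposure–outcome backdoor paths and,
jointly with the exposure, the mediator–outcome backdoor paths; the
search enumerates minimal sets satisfying both. When several minimal
sets exist the pipeline takes the smallest, breaking ties
lexicographically on sorted node names, and logs the choice —
determinism is worth more here than any substantive preference
between equally valid sets.

The bundled `dag_reconstructed.txt` is a synthetic reconstruction: it
encodes a plausible structure over the study's measured variables
(health-literacy, education, HIV status, employment and infant age as
exposure–outcome confounders; parity and delivery mode as causes of
self-efficacy) and is clearly labelled as such. Any analysis of real
data should supply its own DAG file.

## Bootstrap inference

Estimates are accompanied by a nonparametric bootstrap of the entire
pipeline: `B = 1000` resamples of records with replacement by default;
each resample refits both equations and re-simulates the
counterfactual means with a fresh seed derived from the master seed by
replicate counter (so a dropped replicate never shifts another
replicate's stream, and results do not depend on execution order).
Mediator draws are re-randomised per replicate rather than held
fixed — the bootstrap should propagate all sources of variation the
estimator is exposed to.

Per estimand the table reports the point estimate, bootstrap SE,
`z = estimate/SE` with a two-sided normal p-value, the normal interval
`estimate ± 1.96·SE`, and the Efron bias-corrected percentile
interval: `z0 = Φ⁻¹((#{θ* < θ̂} + ½·#{θ* = θ̂})/B)` with bounds at the
nearest-rank empirical quantiles of `Φ(2·z0 ∓ z_α)`. Degenerate cases
are handled explicitly: identical replicates give a zero-width
interval; a count fraction of 0 or 1 is clamped to `½/B` from the
boundary and flagged. Bias correction without acceleration is
deliberate; the accelerated (BCa) variant estimates a skewness
constant the rest of the machinery does not need, and is out of scope.
Replicates whose refits do not converge (e.g. separated logistic fits
in small resamples) are dropped and counted; if more than 5% fail the
run aborts rather than report intervals built on a censored replicate
distribution.

## The synthetic cohort generator

No participant-level data ship with the package, so every stage is
exercised against a generator whose defaults emulate the cohort the
analysis is designed for, with these calibration targets: exposure
prevalence 43%; outcome prevalence 78%; maternal age 29 (6) years;
caesarean section 29%; HIV 20%; household assets 8 of 13; high
health-literacy shares 76% and 70%; infant age with median ~4 days,
IQR 3–7, ~10% beyond 12 days. Confounders are drawn independently
except a positive age–parity link; the real cohort's joint dependence
is unknown, so independence is an explicit simplification, not a claim
about the study.

The mediator is generated as a latent gaussian clipped to the
instrument bounds [14, 70], which reproduces the severe ceiling
observed in this population (over half the cohort at the maximum
score, ~14% below 56). The outcome responds to the high/low
self-efficacy indicator by default (`y_model$mediator = "binary"`),
matching the analysis's default mediator coding. True effect sizes
default to a total causal effect near 0.14 on the risk-difference
scale with a mediated share near 7%; the exposure, mediator and
outcome intercept coefficients were calibrated numerically, once,
so that the marginal prevalences and effects hit those targets
(frozen values in `dgp_config()`).

`true_effects()` computes the generator's oracle-true counterfactual
means by direct simulation from the true structural equations — never
the fitted ones — at 10⁶ records by default (oracle Monte Carlo SE
below 0.001); the committed `recovery_truth.json` fixture records
these values with the exact call that produced them.
`missingness_inject()` adds record-level MCAR missingness for
exercising the listwise-exclusion pipeline; at rate 0.16 on a
201-record cohort the expected exclusion count matches the study's
consort flow (32 excluded, 169 analysed).

**What passing tests do and do not show.** The generator is congenial
with the default analysis: the fitted equations match the true
functional forms up to the linear-probability approximation of the
threshold-crossing probability. Parameter-recovery results therefore
validate the estimator's correctness, not robustness to
misspecification. Real data can violate the DAG, the linearity of the
M-equation, or the logistic form of the Y-equation in ways the
synthetic suite does not probe; the ceiling-heavy mediator is the one
deliberately realistic distortion included.

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares (deviance
  tolerance 1e-10, max 100 iterations). Possible separation — fitted
  probabilities pinned at 0/1 with runaway coefficients — is reported
  as non-convergence, never silently accepted; rank-deficient designs
  abort naming the collinear columns.
* Categorical covariates expand to reference-coded indicators with the
  most frequent level as reference (the source analysis does not state
  its coding; the most frequent level is the stablest baseline).
* The exposure-by-mediator interaction is off by default (none is
  described in this analysis family's specification); enabling it
  requires no change to the decomposition, which works on simulated
  potential outcomes, not coefficient products.
* `NIE = TCE − NDE` holds exactly by construction; the proportion
  mediated is flagged undefined (not NaN) when `|TCE| < 1e-10`.
* All randomness flows from one master seed through labelled
  counter-derived child seeds (`derive_seed()`), making every result
  bit-reproducible and independent of evaluation order.
* Rounding in the text table is half-up to 2 decimals; JSON output
  keeps full precision. Result bundles contain no timestamps, so equal
  seeds give byte-identical bundles (wall-clock goes to `run.log`
  only).

## Problem sizes used by the validation suite

Chosen so the whole suite runs in minutes on a single core, while
keeping each check statistically meaningful:

* Graph oracles: 1000 random DAGs (≤ 10 nodes) for d-separation, 1000
  (≤ 8 nodes) for minimal-set equality.
* Parameter recovery: 200 datasets of n = 2000; the mean of each
  estimate is required to sit within 2 Monte Carlo standard errors of
  the oracle truth.
* Null-path checks: 200 datasets with the mediator–outcome
  coefficient zeroed (n = 2000) and 200 with all exposure coefficients
  zeroed (n = 10 000; the larger n keeps the sampling noise of a null
  total effect below the 0.005 acceptance bound on the median).
* Interval coverage: 500 datasets of n = 600 with B = 200 — a size at
  which the bias-corrected interval is in its asymptotic regime while
  the whole block stays within a few minutes.
* The repeated-measures sensitivity path and the end-to-end
  determinism check run at the study scale (n ≈ 169) with reduced B.

## Ambiguities resolved, and how

* **The mediator's scale in the fitted equations.** The source
  analysis binarised self-efficacy at 56 yet specified linear
  M-equations; both readings are supported. The default follows the
  binarised mediator with a linear (probability) M-equation; `raw`
  keeps the 14–70 score with a gaussian M-equation. The split
  threshold is exposed as `bses_threshold` rather than hard-coded,
  because the reported "median" of 56 is hard to reconcile with over
  half the cohort scoring 70 (56 is more plausibly the lower
  quartile); 56 remains the default.
* **The boundary of the high/low split** is inclusive (a total of
  exactly 56 is "high"), consistent with "below 56" defining the low
  group.
* **Outcome simulation.** Whether the original routine drew Bernoulli
  outcomes or averaged probabilities is unstated; both modes exist and
  agree in expectation, and the lower-variance averaging is default.
* **Repeat visits** are retained only when the second assessment fell
  on a later day than the first; the sensitivity re-run swaps in the
  second-visit mediator, outcome and infant age.
* **Config format.** The run configuration is YAML — the structured
  format with a mature parser in this toolchain — with a documented
  schema and CLI flag overrides.

## Known limitations

* Single mediator, no exposure-induced mediator–outcome confounding,
  no time-varying exposures: the one-shot g-formula only.
* The linear-probability M-equation can clip predictions for extreme
  covariate patterns; clips are counted and reported, but many clips
  signal that the binomial option (or the raw scale) is the better
  model.
* Bootstrap inference is the only inferential route; no analytic or
  sandwich variances are provided.
* At the study's own scale (n ≈ 169) the mediated-path estimate is
  dominated by sampling noise (bootstrap SE on the indirect effect of
  the same order as the estimate); the package reproduces that
  honestly rather than stabilising it.
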