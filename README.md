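# gcompmed

Counterfactual mediation analysis by Monte Carlo G-computation, with
bias-corrected bootstrap inference — built for the question of whether
perceived support from nurses in the first days postpartum affects
exclusive breastfeeding, and how much of that effect runs through
breastfeeding self-efficacy. The package is equally usable for any
binary-exposure / single-mediator / binary-outcome mediation problem
with baseline confounders.

## Who it is for

Epidemiologists and applied biostatisticians who want the
counterfactual (natural-effects) decomposition of a total effect into
direct and mediated components on the risk-difference scale, with the
whole estimation pipeline — variable derivation from questionnaire
items, DAG-based adjustment-set selection, model fitting, simulation,
and bootstrap — reproducible from one seed.

## The method

For exposure X, mediator M, outcome Y and confounders C, the g-formula
estimates the counterfactual outcome means

```
mu_11 = E[Y(1, M(1))]    mu_00 = E[Y(0, M(0))]    mu_10 = E[Y(1, M(0))]
```

by fitting a linear M-equation `M ~ X + C_M` and a logistic Y-equation
`Y ~ X + M + C_Y`, simulating each record's mediator under the
exposure override, and averaging the fitted outcome probabilities over
records and mediator draws. The effects follow as

```
TCE = mu_11 - mu_00          (total causal effect; an ATE)
NDE = mu_10 - mu_00          (natural direct effect)
NIE = TCE - NDE              (natural indirect effect)
proportion mediated = NIE / TCE
```

`C_M` and `C_Y` are minimal sufficient adjustment sets computed from a
user-supplied causal DAG by exact d-separation (moralised ancestral
graph) and exhaustive minimal-set search. Inference is a nonparametric
bootstrap of the entire pipeline (default B = 1000) with normal and
Efron bias-corrected percentile intervals.

## Worked example

No participant data are distributed, so the example runs on the
built-in synthetic cohort generator, calibrated to the study regime
(n = 169; 43% exposed; 78% exclusively breastfeeding; ceiling-heavy
self-efficacy score):

```r
library(gcompmed)

dag    <- read_dag(system.file("extdata", "dag_reconstructed.txt",
                               package = "gcompmed"))
cohort <- dgp_generate(dgp_config(n = 169, rng_seed = 2026))
inference <- gcomp_bootstrap(cohort, dag = dag, B = 1000, rng_seed = 2026)
inference
```

```
      G-estimate  Bootstrap SE z-statistic p-value  95% CI          95% CI (BC)
TCE   0.17        0.07         2.39        0.02     0.03 to 0.31    0.02 to 0.30
NDE   0.15        0.07         2.00        0.05     0.00 to 0.29    -0.01 to 0.29
NIE   0.02        0.02         1.32        0.19     -0.01 to 0.06   -0.00 to 0.07

Proportion mediated: 14%
Bootstrap replicates: 1000 requested, 0 failed
```

Read: in this simulated cohort, mothers who find nurses always helpful
have a 17-percentage-point higher probability of exclusive
breastfeeding (bias-corrected 95% CI 0.02 to 0.30); only 2 points of
that run through self-efficacy, and the mediated path is not
distinguishable from zero at this sample size. The generator's true
values (TCE 0.142, NDE 0.132, NIE 0.010 — see
`inst/extdata/recovery_truth.json`) sit inside the intervals; a single
n = 169 draw is noisy by design.

The same analysis runs from the shell over a CSV and a YAML config
(see `inst/extdata/config_example.yaml`):

```sh
Rscript inst/cli/gcompmed run-all --config config.yaml --seed 2026
```

with subcommands `derive`, `adjust`, `estimate`, `bootstrap`,
`simulate` for the individual stages. The result bundle (derived
table, exclusion log, adjustment-set report, inference JSON and text
table, manifest) is byte-identical across reruns with the same seed.

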