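# psurro

Principal-stratification tools for deciding whether a post-randomization
biomarker is a useful **surrogate endpoint** in a two-arm randomized trial
with a binary clinical outcome.

## The problem and the estimands

A biomarker `S` measured at a fixed time τ after randomization is a
*principal surrogate* when the treatment effect on the clinical outcome `Y`
tracks the treatment effect on the biomarker. Because `S` is measured after
treatment, naive conditioning on its observed value is confounded; principal
stratification conditions instead on the pair of potential biomarker values
`(S0, S1)` under control and treatment — a baseline characteristic — and
compares the per-stratum risks

    R_z(s0, s1) = P(Y_z = 1 | S0 = s0, S1 = s1, A0 = A1 = 1),  z = 0, 1,

where `A_z` indicates that the biomarker is defined at τ under assignment
`z`. Surrogate value is judged through the risk difference `RD = R1 − R0`
(or relative risk `R1/R0`): **average causal necessity** (`RD = 0` where
`s1 = s0`) and **average causal sufficiency** (`RD ≠ 0` where
`|s0 − s1| > C`).

No parallel-arm trial observes `(S0, S1)` jointly, so these estimands are
not identified without assumptions. The package implements the full ladder:

- **data model** — trial CSV I/O with an explicit *undefined biomarker*
  sentinel, quantile discretization, validation diagnostics;
- **simulator** — counterfactual trials with known closed-form truth,
  including controllable assumption violations, the test bed for every
  estimator (`simulate_counterfactual_trial`, `mask_to_observed`,
  `true_estimands`);
- **oracle estimands** — direct and Bayes-decomposed per-stratum risks on
  counterfactual tables, contrasts, and the necessity/sufficiency verdict
  (`oracle_risks`, `oracle_risks_bayes`, `risk_contrasts`,
  `classify_surrogate`);
- **identification under simplifying assumptions** — the treated risk curve
  `R1(s1)` is nonparametrically identified when biomarkers are defined on
  everyone and the control biomarker is constant
  (`estimate_r1_under_sa2`); the non-identified control curve is explored
  by an exponential-tilt sensitivity family with feasibility flags
  (`sensitivity_r0`);
- **augmented designs** — closeout measurement of event-free controls plus
  the mixture identity
  `f(s1|Y0=1) = [f(s1) − f(s1|Y0=0) P(Y0=0)] / P(Y0=1)` for full
  identification (`estimate_full_surface_closeout`), baseline-predictor
  bridge imputation with the observed risk model
  `g(R_z) = α0 + α1 z + α2 θ(S0,S1) + α3 z·θ(S0,S1)`
  (`fit_bridge_models`, `fit_risk_model`), and crossover identification
  (`estimate_from_crossover`);
- **diagnostics and bounds** — the testable implication
  `P(Y1=1) ≤ P(Y0=1)` of outcome monotonicity
  (`test_monotonicity_implication`) and sharp per-stratum
  partial-identification bounds computed as linear programs over the
  probability simplex (`partial_id_bounds`);
- **uncertainty** — arm-stratified subject-level bootstrap around any
  estimator (`bootstrap_ci`);
- **CLI** — `psurro_run()` / `inst/cli/psurro` expose `simulate`, `oracle`,
  `estimate`, `sensitivity`, `closeout`, `bridge`, `bounds`, `report` with
  JSON run manifests.

## A worked example

```r
library(psurro)
expit <- function(x) 1 / (1 + exp(-x))

cfg <- sim_config(n = 50000, k = 5, mode = "sa2", c_value = 0,
                  s1_pmf = rep(0.2, 5),
                  risk0 = 0.3,
                  risk1 = expit(qlogis(0.3) - 0.5 * 0:4),
                  seed = 1)
cf  <- simulate_counterfactual_trial(cfg)
obs <- mask_to_observed(cf, assign_p = 0.5, seed = 2)
obs <- simulate_closeout(cf, obs, cfg)

estimate_r1_under_sa2(obs, cfg$support)
#>   s0 s1 r0         r1    n
#> 1  0  0 NA 0.29517351 5014
#> 2  0  1 NA 0.21475010 4922
#> 3  0  2 NA 0.14294152 5079
#> 4  0  3 NA 0.08174442 4930
#> 5  0  4 NA 0.04956727 5084
```

The treated risk curve declines from ≈0.30 at the null stratum to ≈0.050
at the top stratum — the per-stratum probability of the clinical outcome
under treatment, identified entirely from the treated arm. Adding the
closeout measurements identifies the control curve too:

```r
est <- estimate_full_surface_closeout(obs, cfg$support)
est
#> <closeout_estimate> P(Y0=1) = 0.3007  clipped mass = 0
#>   s0 s1        r0         r1    n
#> 1  0  0 0.3087292 0.29517351 5014
#> 2  0  1 0.2760550 0.21475010 4922
#> 3  0  2 0.3142210 0.14294152 5079
#> 4  0  3 0.2790596 0.08174442 4930
#> 5  0  4 0.3241616 0.04956727 5084

classify_surrogate(risk_contrasts(est$surface, "RD"), c_threshold = 0,
                   tol = 0.05)
#> <surrogate_verdict>
#>   average causal necessity:  PASS
#>   average causal sufficiency (C = 0): PASS
#>   smallest C with ACS pass: 0
#>   tolerance: 0.05
```

The recovered control risks sit near the generating value 0.3 on every
stratum, the risk difference vanishes on the diagonal stratum and is
material off it, so the biomarker passes both surrogate criteria at the
stated tolerance. The same analyses run from a shell:

```sh
inst/cli/psurro simulate --config cfg.json --seed 1 --out trial.csv
inst/cli/psurro estimate --trial trial.csv --assume sa1,sa2 --c-value 0 \
    --k 5 --out r1.csv
```

## Vignette

`vignettes/surrogate-evaluation.Rmd` documents the model, the assumption
ladder, the design decisions (tilt parameterization, clipping policy,
binning conventions) and the simulator's scope.
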