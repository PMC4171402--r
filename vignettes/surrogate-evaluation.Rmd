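---
title: "Evaluating surrogate endpoints by principal stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating surrogate endpoints by principal stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psurro)
expit <- function(x) 1 / (1 + exp(-x))
```

## The problem

A candidate surrogate endpoint is a biomarker $S$, measured at a fixed time
$\tau$ after randomization, that is supposed to predict the effect of
treatment $Z \in \{0, 1\}$ on a binary clinical outcome $Y$. Because $S$ is
measured *after* treatment, conditioning on its observed value can be
confounded by unmeasured common causes of $S$ and $Y$. Principal
stratification avoids that trap by conditioning instead on the *pair* of
potential biomarker values $(S_0, S_1)$ — the values a subject would exhibit
under control and under treatment. That pair is a baseline characteristic,
so treatment remains randomized within each principal stratum and
within-stratum contrasts are genuine causal effects.

The estimands are the per-stratum risks
$$R_z(s_0, s_1) = P(Y_z = 1 \mid S_0 = s_0, S_1 = s_1, A^\tau_0 = A^\tau_1 = 1),
\qquad z = 0, 1,$$
where $A^\tau_z$ indicates that the biomarker is *defined* at $\tau$ under
assignment $z$ (an early clinical event can make a measurement meaningless,
not merely missing — the package carries that as a sentinel, and rejects
missing-but-defined values as out of scope). Surrogate value is judged by
two properties of the risk-difference surface $RD = R_1 - R_0$ (or the
relative-risk surface $R_1 / R_0$):

* **average causal necessity** — $RD(s_0, s_1) = 0$ wherever $s_1 = s_0$:
  no biomarker movement, no clinical effect;
* **average causal sufficiency** — $RD(s_0, s_1) \neq 0$ wherever
  $|s_0 - s_1| > C$ for some constant $C \geq 0$: enough biomarker
  movement guarantees a clinical effect.

These are exact population statements. On estimates the package
operationalizes them with an equality tolerance (default 0.02 on the risk
difference; there is no canonical finite-sample decision rule) and also
reports the smallest $C$ at which sufficiency holds, since $C$ itself is
not pinned down by the definition.

The central difficulty is that no parallel-arm design observes $(S_0, S_1)$
— or $(Y_0, Y_1)$ — jointly on any subject, so the estimands are not
identified without further assumptions. Everything in this package is
organized around that fact: what becomes identified under which assumption,
what to do with the parts that remain unidentified, and how augmented
designs buy identification back.

## The simulator is the source of truth

Because joint counterfactuals are unobservable in real data, every
estimator here is validated against `simulate_counterfactual_trial()`,
which draws the full potential-outcome table from a declared generating
model and therefore knows the true estimands in closed form
(`true_estimands()`). `mask_to_observed()` then realizes randomization and
consistency, producing the realizable view an estimator would actually see.

The canonical configuration used throughout the tests ("five-level,
constant control") has $K = 5$ biomarker levels $0, \dots, 4$, uniform
$S_1$, constant $S_0 = 0$, flat control risk $R_0 \equiv 0.3$, and a
treated risk declining in the stratum on the log-odds scale,
$R_1(s) = \operatorname{expit}(\operatorname{logit}(0.3) - 0.5 s)$. Its
diagonal stratum has zero risk difference by construction, so the truth
satisfies necessity, and every off-diagonal stratum has a nonzero effect,
so it satisfies sufficiency with $C = 0$. Default sample sizes in the
validation suite (200&nbsp;000 for identification checks, 100&nbsp;000 for
augmented-design recovery, 1000 per arm for diagnostic power) are chosen so
that Monte Carlo noise sits well below the assertion tolerances; the
methods are nonparametric per-stratum proportions, so the per-stratum
standard error $\sqrt{p(1-p)/n_s}$ with $n_s \approx n/(2K)$ gives
$\approx 0.003$ at the largest sizes.

Design choices in the simulator worth knowing:

* **Outcome monotonicity is pathwise.** With `monotone_y = TRUE` the two
  potential outcomes are thresholded against a *single* shared uniform
  (comonotone coupling), so $P(Y_1 \le Y_0) = 1$ holds subject by subject,
  not merely in distribution. This requires $R_1 \le R_0$ per stratum.
* **Undefined biomarkers are outcome-linked on purpose.** The `a_model`
  gives $P(A_z = 0 \mid Y_z)$ per arm, mirroring the motivating situation
  of a clinical event preceding the measurement time. Setting the
  probabilities equal across outcome levels gives benign, ignorable
  undefinedness; unequal values create controlled violations of the
  all-defined assumption.
* **Closeout drift is one interpretable knob.** `closeout_delta` shifts
  closeout measurements by whole support levels (ends absorbing);
  `closeout_delta = 0` is exact time constancy.
* **What the simulator does not emulate:** interference between subjects,
  per-subject measurement times, drop-out (missing-but-defined values),
  time-to-event outcomes, and continuous-time infection processes. Passing
  tests therefore certify the estimators under the stated generative
  contracts, not robustness to these real-data features.

## Identification layers

**Layer 1 — all biomarkers defined.** If $A^\tau = 1$ for everyone, the
conditioning on $(A^\tau_0, A^\tau_1)$ drops and the risks decompose by
Bayes' rule into marginal event rates (identified by randomization) and
biomarker densities within outcome groups. `oracle_risks()` and
`oracle_risks_bayes()` compute the direct and decomposed forms on
counterfactual tables; their agreement to $10^{-12}$ on arbitrary finite
tables is the suite's first acceptance property, because the decomposition
is the algebraic backbone of every later identification step. When a small
fraction of subjects has undefined biomarkers, estimators discard them
with a loud warning up to a configurable cap (default 5%; the assumption
is only tenable when the fraction is very small) and refuse beyond it.

**Layer 2 — constant control biomarker.** If $S_0 = c$ for everyone (a
drug metabolite absent without treatment, a vaccine-specific immune
response in naive subjects), strata collapse to $S_1$ alone and
$R_1(s_1) = f(s_1 \mid Y_1 = 1) P(Y_1 = 1) / f(s_1)$ is fully identified
from the treated arm: `estimate_r1_under_sa2()` computes it both as the
plug-in Bayes form and as the per-stratum event proportion and enforces
their algebraic identity internally. Plug-in empirical pmfs are used
without smoothing, matching the nonparametric identifiability framing; the
default discretization for continuous markers is $K = 5$ quantile bins
(left-closed, ties to the lower bin) — small enough for per-stratum
estimation at realistic trial sizes, large enough to display a
dose-response shape. Quantile binning itself is this package's choice; the
identifiability theory only requires discreteness.

$R_0(s_1)$ remains unidentified because it needs
$f(s_1 \mid Y_0 = 1)$ — the treated-arm biomarker distribution that
*control-arm cases* would have shown. `sensitivity_r0()` indexes this
unknown by a one-parameter exponential tilt
$f_\beta(s_1 \mid Y_0 = 1) \propto f(s_1)\, e^{\beta\, \mathrm{rank}(s_1)}$:
$\beta = 0$ is "cases look like everyone" (no selection), and the sign and
magnitude of $\beta$ say where cases concentrate. The tilt is a faithful
but non-unique realization of "vary the case distribution away from the
marginal"; a list of user-supplied scenario pmfs is accepted as an
alternative. Each family member is checked for *mixture feasibility* —
the implied distribution among non-cases must be a valid pmf, i.e.
$f_\beta(s_1 \mid Y_0=1) P(Y_0=1) \le f(s_1)$ coordinate-wise — and the
feasible set is an interval in $\beta$ (the violated coordinate's mass
ratio is monotone in $\beta$), which the suite property-tests.

**Layer 3 — monotonicity.** `test_monotonicity_implication()` tests the
observable implication $P(Y_1{=}1) \le P(Y_0{=}1)$ of the individual-level
assumption (pooled one-sided normal approximation, Fisher's exact test
below 30 events per arm). The distribution-level stochastic-ordering
assumption constrains the unknown case distribution's CDF to lie at or
below the identifiable CDF of $S_1 \mid Y_1 = 1$ and feeds the bounds
below.

## Partial identification

`partial_id_bounds()` treats $p = f(s_1 \mid Y_0 = 1)$ as a free point on
the $K$-simplex and extremizes each stratum's risk difference
$r_1(s) - p(s) P(Y_0{=}1)/f(s)$ over the polytope cut out by the selected
constraints (mixture feasibility always; optionally the monotone-outcome
lower bound $p(s) \ge r_1(s) f(s)/P(Y_0{=}1)$ and the stochastic-order CDF
constraints). Each extremum is a small linear program (solved with the
simplex method); per-stratum extremization over the shared polytope is the
canonical sharp choice given that the literature gestures at "bounding"
without prescribing a functional. The bounds inherit three testable
properties: they match a brute-force grid search over the simplex on
3-level miniatures, they never widen when a constraint is added, and they
cover the true risk difference whenever the generating model satisfies the
imposed constraints. Degenerate polytopes (constraints pinning $p$ to a
point) yield point identification; infeasible constraint sets are reported
with the offending constraint named, never silently relaxed. Sampling
uncertainty of the plugged-in inputs is *not* inside these bounds — they
are identification bounds; wrap the pipeline in `bootstrap_ci()` for
confidence statements.

## Augmented designs

**Closeout.** Control subjects who end the study event-free receive the
active treatment and have their biomarker measured; under *time constancy*
(the treated-biomarker-generating process did not drift over the study)
those measurements identify $f(s_1 \mid Y_0 = 0)$, and the mixture
identity
$$f(s_1 \mid Y_0 = 1) = \frac{f(s_1) - f(s_1 \mid Y_0 = 0)\,P(Y_0 = 0)}
{P(Y_0 = 1)}$$
recovers the missing case distribution — full identification.
`recover_f_s1_given_y0_1()` applies the identity coordinate-wise; at the
population level the result is a valid pmf, but sampling noise can push
coordinates negative, so negatives are clipped to zero, the pmf
renormalized, and the clipped mass reported (silent negative probabilities
would corrupt every downstream contrast; the identity itself gives no
guidance here, so clip-and-report is this package's policy).
$P(Y_0 = 1)$ is taken from the *full* control arm — the identity needs the
marginal control risk, and outcomes are observed even where biomarkers are
not.

**Bridge imputation.** Baseline covariates $U, V$ that predict $S_0, S_1$
support cross-arm imputation: $g(E[S_0 \mid U])$ is fit on the control arm
only, $g(E[S_1 \mid V])$ on the treated arm only (validity rests on
randomization giving $(S_0, S_1) \perp Z \mid U, V$; the no-leakage
property is tested by permuting the other arm's covariates). Imputed
values are re-binned to the support, and the completed table feeds the
observed risk model
$g(R_z) = \alpha_0 + \alpha_1 z + \alpha_2 \theta(S_0, S_1) +
\alpha_3 z\,\theta(S_0, S_1)$, with $\theta$ a pre-declared scalar summary
(default $s_1 - s_0$, reducing to $s_1$ under a constant control biomarker
at 0) and a logit link by default (identity is available but warns when
predictions leave $[0,1]$). The risk model is fit on *all* rows, each
using its observed own-arm and imputed other-arm biomarker; fitting on one
arm only is equally defensible and the choice is recorded in the output.
Mean imputation is the default; stochastic imputation (fitted value plus a
seeded residual draw) exists to propagate imputation noise through the
bootstrap rather than to support multiple-imputation pooling, which is out
of scope. The baseline-irrelevant-vaccination strategy is the treated-side
model with $V$ the response to an unrelated baseline vaccine.

**Crossover.** Where washout is adequate, both pairs $(S_z, Y_z)$ are
observed per subject and `estimate_from_crossover()` simply runs the
oracle computation on the paired table — full identification with no new
machinery. Carryover modeling is deliberately absent; washout adequacy is
the analyst's assertion.

## Numerical and degenerate-input policy

* Empty strata are omitted and listed, never imputed: the estimands are
  undefined off the support of the stratum distribution.
* Relative risks with a zero denominator are flagged, not infinite, so
  surfaces serialize cleanly.
* All pmfs must sum to 1 within $10^{-12}$ at configuration time and
  within $10^{-9}$ after estimation; risks are clamped to $[0,1]$ only
  where a mixture inversion's sampling noise can exceed the range, and the
  clip is visible in the reported negativity mass.
* Every stochastic function takes an explicit seed; identical
  configuration and seed give byte-identical tables, and the CLI records
  seeds and input digests in a run manifest.
* Ties at discretization bin edges go to the lower bin; the last bin is
  closed.

## A worked example

```{r example}
cfg <- sim_config(n = 50000, k = 5, mode = "sa2", c_value = 0,
                  s1_pmf = rep(0.2, 5),
                  risk0 = 0.3,
                  risk1 = expit(qlogis(0.3) - 0.5 * 0:4),
                  seed = 1)
cf <- simulate_counterfactual_trial(cfg)
obs <- mask_to_observed(cf, assign_p = 0.5, seed = 2)
obs <- simulate_closeout(cf, obs, cfg)

# identified treated risk curve
estimate_r1_under_sa2(obs, cfg$support)

# closeout identifies the control curve too
est <- estimate_full_surface_closeout(obs, cfg$support)
est

# and the surrogate verdict at the recovered surface
classify_surrogate(risk_contrasts(est$surface, "RD"), c_threshold = 0,
                   tol = 0.05)
```

## Known limitations

The package evaluates one biomarker at one measurement time against one
binary outcome. It does not handle time-to-event outcomes, repeated
biomarker measurements, per-subject measurement times, interference
between subjects, missing-but-defined biomarker values, two-phase sampling
estimators, or Bayesian model-based estimation of the non-identified
components — the sensitivity family and the bounds are the supported
answers to non-identification. The finite-sample behavior of the
necessity/sufficiency classifier depends on its tolerance; at small
per-stratum counts the verdicts are noisy and should be read alongside
bootstrap intervals.
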