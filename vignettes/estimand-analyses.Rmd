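---
title: "Estimand-aligned analyses of short-term depression trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimand-aligned analyses of short-term depression trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-term antidepressant trials measure the MADRS10 total score (0-60,
lower = less severe depression) at baseline and at a handful of weekly
post-baseline visits.  Patients discontinue treatment - mostly for adverse
events (AE) early in the trial or lack of efficacy (LoE) later - and the
outcomes after discontinuation are usually missing.  Under the ICH E9(R1)
estimands framework, every familiar analysis of such a trial (ANCOVA on
completers, LOCF, multiple imputation, MMRM, reference-based imputation,
pattern-mixture models, principal stratification) implicitly answers a
*different* clinical question, determined by how the analysis handles the
intercurrent event of treatment discontinuation.

`estimandr` implements those analyses behind one uniform interface, a
catalog that maps each method to the estimand(s) it targets, and a
synthetic-trial generator that knows the true value of every estimand, so
each estimator can be validated against the target it claims to estimate.

## The data model

A trial is a `trial_dataset`: a subject table (id, arm, baseline,
discontinuation reason and visit) plus an n-by-V outcome matrix for the V
post-baseline visits.  The baseline is a covariate, never part of the
outcome vector.  A recorded discontinuation at visit d implies the
monotone-tail invariant: all outcomes after d are missing.  Subjects are
classified into three dropout patterns from the length of the trailing
run of missing outcomes alone:

* **completers/quasicompleters** - last visit observed, or only the last
  visit missing (earlier gaps may be intermittent);
* **late dropout** - a monotone missing tail of exactly the last two
  visits;
* **early dropout** - a monotone tail of three or more visits.

An all-missing outcome vector is unclassifiable and such subjects are
excluded from likelihood-based fits (with a warning) while still counting
in the intercurrent-event denominators.  For a three-visit schedule the
trailing-run rule is the natural generalisation; there a two-visit tail is
labelled late dropout and an early-dropout pattern cannot occur (a longer
tail would leave no post-baseline data).

## The synthetic-trial generator

`sim_config()` + `simulate_trial()` emulate the structure the analyses
assume:

```
Y_ij = mu[arm, j] + gamma (baseline_i - mean) + b_i + e_ij,
b_i ~ N(0, sigma_b^2),  e_i ~ N(0, Serial),
```

with baselines truncated below at 10 points (a severity cut-off),
scores clipped to [0, 60], and discontinuation drawn from per-reason
discrete-time logistic hazards: LoE risk increases with the current
score, AE risk is restricted to an early visit window, and smaller
constant hazards cover drug-unrelated, unknown, efficacy and compliance
reasons.  Intermittent MCAR blanking is applied independently.  The
defaults give a 2-arm, 6-visit trial with baselines around 30 points, a
placebo response of about 8 points, an active effect growing to -4 points
at week 6, and roughly a quarter of subjects discontinuing, LoE-dominant
and placebo-heavy - the regime the package's validation suite exercises.

Design choices worth knowing:

* **Scores stay continuous by default** (`integer_scores = FALSE`) so
  Gaussian parameter-recovery checks are exact in expectation; rounding is
  available for cosmetic realism.
* **Clipping applies to emitted scores only**; the hazards see the latent
  values.  At the default configuration clipping is rare and its effect on
  the week-6 contrast is a few hundredths of a point.
* **Named seed substreams** (baseline, random effects, residuals, dropout,
  intermittent, per-imputation) make every output a pure function of
  (config, seed) and let one mechanism be toggled without disturbing the
  draws of the others.
* **Ground truth**: the generator records potential-outcome matrices for a
  no-event (hypothetical) world and for the configured post-event world
  (`MAR_CONTINUATION`, `J2R_SWITCH`, or `RETAINED_SLOPE`), so
  `true_estimand_value()` can report the finite-sample truth for the
  hypothetical, treatment-policy, while-on-treatment and principal-stratum
  estimands.  The principal-stratum truth uses subjects event-free under
  their *own* assignment - a single-world approximation of the cross-world
  stratum; a joint-counterfactual simulation is out of scope.

What the generator does **not** emulate: active-comparator
pharmacology, continuous-time dropout, site effects, or item-level MADRS
structure.  Passing tests therefore demonstrate internal validity of the
estimators under the assumed longitudinal Gaussian model, not performance
on any particular real trial.

## The MMRM

The core model is the saturated mixed model for repeated measures

```
Y_ij = b0 + b1 Trt_i + b2F Time_ijF + b3F Time_ijF Trt_i
       + b4 Baseline_i + (within-subject error),
```

with visit 1 as the reference level, the baseline entered uncentred, and
the visit-specific treatment effect at the last visit

```
delta_V = b1 + b3V.
```

Between-patient variation (random intercepts) plus an unrestricted serial
correlation are not separately identified when the serial structure is
unstructured, so the package fits a single **unstructured total**
within-subject covariance - the same marginal model, one parameterisation.
Estimation is REML: the covariance is parameterised by the log-Cholesky
factor (positive-definiteness by construction), coefficients are profiled
out by GLS, and a quasi-Newton optimizer uses the analytic gradient of
the restricted log-likelihood.  Subjects contribute the sub-matrix of the
covariance at their observed visits, which is exactly the
direct-likelihood treatment of intermittent and monotone missingness
(valid under MAR).

Numerical choices: starting covariance = diagonal of per-visit observed
variances; relative log-likelihood tolerance 1e-8 (tighter on request);
at most 200 iterations with one jittered restart; proposals whose
covariance or normal-equations matrix fails a Cholesky factorisation are
rejected with a penalty value.  Inference uses the normal approximation
throughout (z intervals; Rubin's t for pooled MI results).  Small-sample
degree-of-freedom corrections (Satterthwaite/Kenward-Roger) are out of
scope: at the sample sizes the package targets (dozens per arm) the
difference is negligible relative to the between-method differences the
package is built to expose.

```{r}
library(estimandr)
sim <- simulate_trial(sim_config(n_per_arm = 50), seed = 1)
fit <- reml_fit(sim$dataset)
treatment_effect_at_visit(fit, visit = 6)
```

## Imputation methods

**LOCF** fills each missing cell with the most recent observed
post-baseline value.  For missing cells *before* the first observed
post-baseline value the baseline is carried (it is the last observation
at that point); the count of baseline-carried cells is reported, since
this fallback is a convention rather than a consequence of the method's
definition.

**PMM multiple imputation** is chained-equations predictive mean matching
with predictors treatment, baseline, and the current values of all other
visits; parameters are drawn from the standard noninformative-prior
posterior, and each missing value receives an observed value of one of
the 5 nearest donors by predicted mean (ties broken uniformly at random
within the imputation's substream).  Defaults: m = 10 imputations, 10
sweeps, 5 donors.  Imputations always lie on the observed support of the
visit.

**Jump-to-reference** fits the MMRM on the reference arm only (intercept,
visit indicators, baseline) and imputes each experimental-arm
post-discontinuation cell as the reference fixed-part prediction plus a
random error.  The default draws the errors independently per visit from
the reference marginal variances - the literal reading of the procedure
this package follows; `draws = "joint"` instead draws the missing block
jointly from the reference covariance.  Either way the prediction
conditions only on baseline and visit, not on the subject's own observed
history.  Imputed values are not rounded and not clipped; reference-arm
and pre-discontinuation intermittent cells are left to the downstream
MMRM likelihood as MAR.

**Rubin's rules** pool the per-imputation (estimate, SE) pairs of the
final contrast - never whole coefficient vectors - with total variance
`W + (1 + 1/m) B` and the usual degrees of freedom (infinite, hence
normal quantiles, when B = 0).

## Pattern-mixture and principal-stratum analyses

The **pattern-mixture** model adds pattern main effects and
pattern-by-treatment interactions to the MMRM: a level offset and a
constant treatment-effect shift per pattern, with a shared visit-time
profile (no pattern-by-time terms).  The overall effect is the weighted
average of pattern-specific week-V effects, weighted by the analyzed
sample's pattern frequencies; the SE uses the model covariance of the
pattern contrasts with the weights treated as fixed constants
(weight-estimation variance is deliberately ignored and documented).  A
pattern with fewer than 2 subjects in any arm would make its interaction
inestimable, so sparse patterns are merged stepwise - early into late,
late into completers - and the merge is recorded in the diagnostics.  With
a single remaining pattern the model *is* the plain MMRM.

The **principal-stratum** analysis regresses the event indicator (any
discontinuation by default) on baseline, pooled across arms, and selects
subjects whose predicted event propensity falls below a cutoff; the MMRM
is then fitted on that stratum without imputation.  The `"AUTO"` cutoff
is the propensity quantile equal to the observed event-free fraction, so
the stratum matches the event-free share of the sample; a numeric cutoff
(including 1, selecting everyone) may be supplied.  Under separation the
logistic fit falls back to a small ridge penalty - the propensity ranking,
and hence the selection, is unaffected.  When no events occurred at all
the stratum is the whole population and the analysis reduces to the
MMRM.  Covariates and the event definition are configurable; baseline-only
is the default because it is the only predictor guaranteed to exist in
the minimal data model.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* pattern classification against a literal brute-force rule enumeration
  over all missingness masks;
* the REML engine against a naive direct-likelihood optimizer (explicit
  per-subject inversions, a different covariance parameterisation) on
  small fixtures, and against `nlme::gls` on complete data;
* Rubin pooling against hand arithmetic;
* exact reductions (single-pattern PMMM = MMRM, cutoff-1 stratum = MMRM,
  no-missing imputation pipelines = their plain counterparts);
* stochastic properties on generated trials: parameter recovery and CI
  coverage for the MMRM, mechanism-matched consistency of
  jump-to-reference under a true switch to reference, attenuation of
  jump-to-reference when the truth is MAR continuation, and inflation of
  LOCF estimates under score-dependent LoE dropout.

Simulation sizes were chosen to keep the full suite comfortably inside a
desk-scale run: 200 replicate trials of 100 subjects/arm for recovery,
500 for coverage, 60 replicates of 150/arm with m = 10 imputations for
the reference-based checks, and 50 seeds for the directional and
concordance properties.  All Monte-Carlo tolerances are expressed in
multiples of the Monte-Carlo standard error, so they scale with the
replication counts rather than being tuned numbers.

## Limitations

* Inference is asymptotic; very small trials (a handful of subjects per
  arm) are rejected rather than corrected.
* The catalog encodes the mapping for the eight implemented methods only;
  delta-adjustment/tipping-point sensitivity analyses and
  copy-increments-in-reference variants are not implemented.
* Reason codes are carried through but all discontinuations are treated
  as one intercurrent event ("study withdrawal"); per-reason strategy
  differentiation is a data-collection problem the minimal data model
  cannot solve.
* The generator's cross-world principal-stratum truth is approximated by
  the single-world event-free stratum.
* When the dropout hazard selects on latent subject effects (the
  default score-dependent LoE hazard does), a switch-to-reference world
  that carries the subject's random intercept across the switch and the
  jump-to-reference imputation - which conditions only on baseline and
  visit - target slightly different quantities; the consistency checks
  therefore use a hazard the imputation model matches, and the residual
  selection effect is left visible as a documented caveat rather than
  absorbed into the imputation.
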