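# estimandr

Treatment-effect estimation for short-term depression trials under the
ICH E9(R1) estimands framework.

Longitudinal antidepressant trials measure the MADRS10 score (0–60,
lower = less severe depression) at baseline and a handful of weekly
visits.  Patients discontinue treatment — adverse events early, lack of
efficacy later — and their subsequent outcomes are missing.  Each common
analysis of such a trial implicitly answers a different clinical
question, depending on how it handles that intercurrent event.
`estimandr` implements the full battery behind one interface and makes
the implicit estimand explicit:

| method | strategy for treatment discontinuation |
|---|---|
| `ancova_complete_cases` | hypothetical (valid under MCAR) |
| `ancova_locf`, `mmrm_locf` | while-on-treatment / treatment policy under the LOCF assumption |
| `ancova_mi` | hypothetical under MAR (PMM multiple imputation, Rubin's rules) |
| `mmrm_plain` | hypothetical under MAR (direct likelihood) |
| `mmrm_j2r` | composite / treatment policy under jump-to-reference |
| `pmmm` | composite / treatment policy under pattern-conditional extrapolation |
| `principal_stratum` | effect in the stratum that would not discontinue |

The core model is the saturated MMRM

    Y_ij = b0 + b1 Trt_i + b2F Time_ijF + b3F Time_ijF Trt_i + b4 Baseline_i + eps_ij

with unstructured within-subject covariance estimated by REML
(log-Cholesky parameterisation, analytic gradient, GLS-profiled
coefficients) and the week-V treatment effect `delta_V = b1 + b3V`.  The
pattern-mixture extension adds dropout-pattern terms and reports the
frequency-weighted average of pattern-specific effects
`delta_VP = b1 + b3V + b6P`.

A synthetic-trial generator (`sim_config()`, `simulate_trial()`)
produces trials with the assumed structure — mixed-model MADRS10
trajectories, reason/arm/visit-specific discontinuation hazards, monotone
plus intermittent missingness — together with ground-truth potential
outcomes, so the true value of every estimand is computable and each
estimator can be validated against the target it claims to estimate.

## Worked example

```r
library(estimandr)
sim <- simulate_trial(sim_config(n_per_arm = 50), seed = 1)
run <- suppressWarnings(run_all(sim$dataset, seed = 1, m = 10))
forest_table(run, sim$truth)
```

```
             method estimands estimate   se ci_low ci_high n_used truth
1         ANCOVA_CC        E1    -4.44 1.54  -7.46  -1.427     72 -4.07
2       ANCOVA_LOCF     E2+E3    -4.70 1.59  -7.82  -1.591    100 -4.46
3         ANCOVA_MI     E1+E3    -3.77 1.52  -6.79  -0.754    100 -4.07
4              MMRM     E1+E3    -4.39 1.46  -7.26  -1.525    100 -4.07
5         MMRM_LOCF        E3    -4.70 1.59  -7.82  -1.587    100 -4.07
6          MMRM_J2R     E3+E4    -3.81 1.46  -6.66  -0.956    100 -4.07
7              PMMM     E3+E5    -4.73 1.52  -7.70  -1.756    100 -4.07
8 PRINCIPAL_STRATUM        E6    -4.32 1.74  -7.74  -0.900     75 -3.77
```

One hundred subjects, 16.7% missing outcome cells, a true hypothetical
week-6 effect of −4.07 points in this sample.  Each row is one analysis
with its estimate, SE, 95% CI, the estimand ids it targets (`E1`
hypothetical, `E2` while-on-treatment, `E3` treatment policy, `E4`/`E5`
composites, `E6` principal stratum) and the generator's true value of
the first targeted estimand.  The familiar qualitative pattern is
visible: LOCF-based analyses give the largest effects (dropout under
lack of efficacy freezes bad placebo scores), jump-to-reference is
attenuated toward the null, MMRM and the pattern-mixture model agree
closely.

`estimand_catalog()` returns the six-estimand catalog with populations,
variables, summaries and required missing-data assumptions;
`sensitivity_pairs()` lists which analyses can serve as sensitivity
analyses for each other (those sharing an estimand — e.g. MMRM for
complete-case ANCOVA on E1 — and not, e.g., the two composite analyses,
which differ in the variable attribute).

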