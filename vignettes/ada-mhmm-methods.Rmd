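---
title: "Modelling hidden anti-drug-antibody dynamics from PK residuals and ADA assay data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hidden anti-drug-antibody dynamics from PK residuals and ADA assay data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adamhmm)
```

## The problem

Biologic drugs can provoke anti-drug antibodies (ADA). ADA that bind the
drug may accelerate its elimination and cause treatment failure, but the
assays used to measure ADA are imperfect: high circulating drug
concentrations can mask ADA (false negatives), assays can cross-react (false
positives), and a subject is usually called "positive" only once a
measurement crosses a clinical threshold — by which time the pharmacokinetic
(PK) consequences may long have been present.

`adamhmm` treats ADA production as what it really is: an unobserved,
time-varying state. A two-state hidden Markov model links that state to two
observed variables that each carry partial information:

* **Weighted PK residuals** (`IWRES`). A population PK model *without* any
  ADA effect is fitted to first-dosing-occasion data (when subjects are drug
  naive and ADA-free) and then predicts all later occasions. While no ADA are
  produced the residuals are centred near zero with SD near 1; once ADA
  increase clearance, the model over-predicts and the residuals drift
  negative.
* **ADA assay measurements**, reported in U/mL with a lower limit of
  quantification (LLOQ) of 0.6 U/mL (values below are reported *at* the
  limit) and a clinical positivity threshold of 2.4 U/mL.

## The model

### Hidden layer

Two states: `S_NOADA` (no production) and `S_ADA` (production). Subjects are
drug naive at entry, so everyone starts in `S_NOADA`; no stationary
distribution is estimated. Only two transition probabilities are free,
`pi12` (`S_NOADA` to `S_ADA`) and `pi21` (back), both modelled on the logit
scale; the diagonal of the transition matrix is their complement, so rows
sum to one exactly. The chain advances once per *observation record*, not
per calendar day: the discrete time step is the sampling occasion, and
unequal sampling intervals carry no rate adjustment. This is the literal
per-record filtering recursion; a continuous-time variant would be a
different model.

### Emission layer

Given the state, the two observed variables follow a bivariate Gaussian
with state-specific modes and correlations and *shared* per-variable
variances. Sharing the variances across states is deliberate: most ADA
measurements sit at the LLOQ, and a state-specific `S_NOADA` variance would
collapse toward zero and destabilize the likelihood. When one variable is
missing at a record (e.g. the single-dose phase-I study contributes no ADA
samples), the exact univariate Gaussian marginal is used; a fully missing
record contributes likelihood one and propagates the state by the
transition alone.

### Filtering and likelihood

The per-subject likelihood uses the scaled forward recursion: the first
record is evaluated under `S_NOADA` alone; each later record propagates the
filtered state probabilities through the transition matrix, multiplies by
the emission densities, and renormalizes. The log-likelihood is the sum of
log normalizers; nothing unnormalized is ever formed, and within each record
the emission log-densities are max-shifted before exponentiation, so cohorts
of any length are safe from underflow.

### Model variants

Six variants are exposed through `variant_config()`:

| variant | ADA modes            | IIV on modes | IIV on transitions |
|--------:|----------------------|--------------|--------------------|
| 1       | estimated            | yes          | yes                |
| 2       | fixed (0.6 / 2.4)    | yes          | yes                |
| 3       | estimated            | no           | yes                |
| 4       | fixed                | no           | yes                |
| 5       | estimated            | no           | no                 |
| 6       | fixed                | no           | no                 |

Fixing the ADA modes at the LLOQ (0.6 U/mL) and the clinical threshold
(2.4 U/mL) deliberately *weights* the observations: a measurement above 2.4
is far more plausible under `S_ADA` than under `S_NOADA`. Variant 6 — fixed
modes, no inter-individual variability (IIV) — is the default and, in the
certolizumab pegol analysis this package takes as its reference case, was
the best-performing variant. `decouple_univariate()` reduces any variant to
a single observed variable (the correlations drop out; the transition
structure is untouched), which quantifies what each variable contributes.

### Inter-individual variability

Where a variant activates IIV, additive normal random effects act on the
emission modes (one shared shift per variable, applied in both states) and
on the transition logits, with independent (diagonal) variances. The
marginal likelihood integrates these out with Gauss–Hermite quadrature
scaled to the prior (default 9 nodes per dimension, configurable). The
quadrature grid is centred on the random-effect prior rather than re-centred
on each subject's conditional mode; with at most a handful of records per
subject the integrand stays close to the prior, and the package's tests
confirm both agreement with dense-grid integration (toy case, relative
1e-6) and 9-vs-15-node stability (< 1e-4). Users fitting cohorts with many
records per subject and large `omega2` should raise `nodes`.

## The population PK stage

The PK model is a one-compartment model with first-order absorption —
the minimal structure consistent with subcutaneous dosing of a molecule
with a ~14-day half-life. Absorption is described by a single `ka` without
IIV: sparse post-dose sampling in the trial designs would not identify more.
Covariates enter as standard pharmacometric forms: an allometric power of
body weight (reference 70 kg) on CL/F and proportional Japanese-ethnicity
shifts on CL/F and V/F. IIV is log-normal on CL/F and V/F and the residual
error is proportional.

The population fit uses only first-dosing-occasion data ("first occasion" =
records strictly before the second dose event; a single-dose study is
entirely occasion 1; in loading-dose designs this is the week-0 to week-2
window). The marginal likelihood is Laplace-approximated: per subject, the
empirical-Bayes (MAP) random effects are located with an analytic gradient
and the curvature term comes from central differences of that gradient.
Algorithm parity with any particular estimation software is not a goal —
what matters downstream is unbiased first-occasion residuals. Individual
parameters then predict *all* occasions, and

```
IWRES = (DV - IPRED) / (sigma_prop * IPRED)
```

is the weighted residual carried into the hidden Markov model (records at or
before the first dose have `IPRED = 0`; their residual is undefined and the
PK component is treated as missing). The proportional-error weighting is
what gives IWRES its expected SD of 1 under a correct model.

A practical caveat the package's own simulations expose: because `IPRED`
appears in the denominator, any residual empirical-Bayes prediction error
`u` inflates the IWRES mean by roughly `Var(u)/sigma_prop`. Under rich
per-subject sampling this is second-order (the mean-zero property holds
comfortably on the 22-sample single-dose design), but under sparse designs
with long extrapolation the pooled IWRES mean sits a few hundredths above
zero. This does not affect the state signal — ADA onset shifts residuals by
more than a full SD — but exact mean-zero checks should be run on rich
designs.

## Estimation

Parameters are estimated by direct maximization of the (quadrature-
integrated) marginal likelihood with a quasi-Newton optimizer in an
unconstrained space: log for variances, logit for probabilities, atanh for
correlations, identity for modes. Default starting values are the prior
expectations (residual modes 0 and −1, variances 1 and 2, zero correlations,
transition probabilities 0.05 and 0.01 — the first being the observed
fraction of clinically positive records in the reference dataset,
368/6898 ≈ 0.05). `n_multistart` adds seeded jittered restarts (±50% on the
natural scale). Convergence uses the optimizer's relative-objective
criterion (1e-10); transition probabilities within 1e-6 of 0 or 1 are
flagged as boundary estimates, which is how a cohort without back-
transitions manifests (`pi21` at ~0 with very large relative standard
error — expected, not an error). Standard errors come from a central-
finite-difference Hessian in the unconstrained space, delta-method mapped to
the natural scale; a non-positive-definite Hessian yields missing SEs and a
flag rather than an exception, mirroring how covariance-step failures are
reported in practice.

Two exact identities are worth recording because they delimit what the
bivariate model adds. With both correlations zero the *emission density*
factorizes, so the bivariate log-likelihood equals the sum of the PK-only
and ADA-only log-likelihoods whenever a single state path carries all
probability mass (single-record series; degenerate chains). With a genuinely
uncertain path the marginal likelihood mixes over paths and the bivariate
log-likelihood generally *exceeds* the factorized sum on data generated from
the model — both variables inform the same hidden path, and that shared
information is exactly what decoupling gives up.

## Viterbi decoding

After fitting, the most likely state sequence per subject is obtained with
the Viterbi algorithm under the same initialization (record 1 in
`S_NOADA`). Ties are broken toward `S_NOADA`, the conservative choice
(fewer false ADA calls) and a deterministic one. Decoded sequences are
summarized per subject (`summarize_paths()`) and compared with the
threshold-based clinical classification (`classify_clinical()`,
`compare_times()`). The persistent/transient label codifies the visual
inspection traditionally used for it: a positive subject whose last two or
more ADA records fall back below threshold is "transient". That rule is a
stand-in, documented as such.

## The cohort simulator

`simulate_cohort()` emulates six subcutaneous trial designs (dose-ranging
Q4W 50–800 mg; 400 mg Q4W phase-III designs; Q2W designs with and without
week-0/2/4 loading doses; a richly sampled single-dose phase-I study without
ADA sampling), totalling 845 subjects at natural sizes. Per subject it draws
covariates and individual PK parameters, evolves the hidden chain per
scheduled record from `S_NOADA`, inflates CL/F by a configurable factor
(default ×2) while in `S_ADA` — the magnitude is a simulator choice, made
configurable precisely because the reference analysis only constrains its
*sign* (over-prediction under ADA) — and emits long-format rows with BLQ
flags (PK floored at 0.41 µg/mL, ADA at 0.6 U/mL). Concentration at a
record is computed with the record's effective clearance (a quasi-stationary
approximation: the inflation is treated as if it had always applied, which
slightly exaggerates the PK signal right at onset and converges to the
correct profile afterwards). PK samples at or before the first dose are
never emitted. An optional log-normal ADA emission (off by default)
emulates the heavy right tail of real assay data. The generator's default
ADA noise SD (0.4 U/mL) is deliberately smaller than the fitted model's
shared emission SD: the latter is an estimation compromise across states,
and using it as generating assay noise would make threshold crossings by
pure noise routine, pushing the emulated clinically-positive fraction far
above the ~10% that trials of this kind report.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: assay drug-tolerance interference (false
negatives from high drug concentrations beyond the LLOQ floor), dropout and
dose modifications, model misspecification of the PK stage (any unexplained
PK change is attributed to ADA, a caveat inherited by the method itself),
and the very large dynamic range of real ADA titres.

`simulate_mhmm()` draws directly from the hidden-Markov model itself
(balanced cohorts, exact Gaussian emissions). By default it does **not**
floor ADA values at the LLOQ: draws then follow the model density exactly,
which is the correct condition for parameter-recovery studies (the floor is
a property of the assay, not of the model, and flooring creates a point
mass at 0.6 that the Gaussian emission cannot represent). Pass
`floor_ada = TRUE` for data that look like assay output;
`simulate_observed_from_fit()` — the posterior-predictive tool — always
applies the floor, since its purpose is comparison with observed data.

## Numerical choices

* Forward recursion: per-record normalization with max-shifted
  exponentiation; log-likelihood accumulated as the sum of log normalizers.
* PK prediction: closed-form superposition over doses; the flip-flop
  degeneracy `ka = CL/V` switches to the analytic limit
  `(D/V) ka t exp(-ka t)` within a relative window of 1e-8 (1e-6 in the
  gradient), never dividing by zero.
* Laplace step: inner mode search with analytic gradients (BFGS, relative
  tolerance 1e-14, warm-started per subject); curvature from central
  differences of the gradient (step 1e-5). Because warm starts leave
  objective noise near the optimizer's tolerance, the outer optimization
  restarts from its incumbent until the objective is stationary before
  declaring convergence.
* Quadrature nodes from the Golub–Welsch Hermite rule
  (`pracma::gaussHermite`), scaled by `sqrt(2) * omega`.
* Dimensions with zero random-effect variance are excluded from the
  quadrature grid, so `omega2 = 0` reproduces the no-IIV likelihood
  exactly.
* Viterbi argmax ties resolve to `S_NOADA` at both the step and the final
  state.

## Problem sizes used in the test suite

Simulation-based tests are sized to be decisive yet quick: parameter
recovery for variant 6 uses 840 subjects × 8 records (trial-sized) and the
rare back-transition check 5000 × 20 (about 60 back-transition events, so
the estimate carries ~13% binomial sampling error — the tolerance used);
replicate-recovery properties use 20 fits of 200 × 8; the population PK
recovery and pipeline tests use 150 subjects with rich first-occasion
sampling and fix `ka` and the covariate effects at their generating values,
estimating the five parameters the design actually informs. Enumeration
oracles cover series up to 12 records (2^11 paths).

## Known limitations

* Per-record (not per-day) transitions: decoded onset times inherit the
  sampling grid's resolution, and cohorts with very different sampling
  densities are not directly comparable on the probability scale.
* The Gaussian ADA emission with LLOQ substitution is a pragmatic
  compromise (as in the reference analysis): it under-represents the mass
  at the floor and the heavy right tail, which is visible in
  posterior-predictive checks of the ADA variable.
* Prior-centred (non-adaptive) Gauss–Hermite quadrature; raise `nodes` for
  long series or large random-effect variances.
* The persistent/transient rule and the CL-inflation magnitude in the
  simulator are explicit stand-ins, not estimated quantities.
* Covariates on transition probabilities are out of scope.

## A minimal workflow

```{r workflow, eval = FALSE}
coh <- simulate_cohort(default_designs(300), seed = 1)
ds  <- as_ada_dataset(coh$data)

pkfit <- fit_first_occasion(ds, default_pk_params(),
                            fixed = c("ka", "theta_wt_cl",
                                      "theta_jp_cl", "theta_jp_v"))
ebes  <- compute_ebes(pkfit, ds)
iw    <- compute_iwres(pkfit, ebes, ds)

rec <- prepare_hmm_records(ds, iw)
fit <- fit_mhmm(rec, variant_config(6), seed = 1, n_multistart = 2, se = TRUE)
fit

decoded <- decode_states(rec, fit)
compare_times(classify_clinical(coh$data), summarize_paths(decoded))
```
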