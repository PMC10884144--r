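# adamhmm

Bivariate mixed hidden-Markov modelling of anti-drug-antibody (ADA)
dynamics from longitudinal pharmacokinetic (PK) and ADA assay data.

## The problem

ADA formed against biologic drugs can accelerate drug elimination and cause
treatment failure, but ADA assays are imperfect: abundant drug masks ADA
(false negatives), assays cross-react (false positives), and subjects are
declared "positive" only after a measurement crosses a clinical threshold —
often long after the PK consequences began. `adamhmm` is for pharmacometric
and immunogenicity analysts who want to infer the *underlying* ADA
production state per subject and time point, pooling two partial signals
instead of trusting either alone.

## The model

A two-state hidden Markov chain — `S_NOADA` (no production) and `S_ADA`
(production) — advances once per observation record; everyone starts in
`S_NOADA` (subjects are drug naive). Only two transition probabilities are
estimated, on the logit scale:

    pi12 = P(S_ADA | S_NOADA),   pi21 = P(S_NOADA | S_ADA)

Conditional on the state, two observed variables follow a bivariate
Gaussian with state-specific modes and correlations and shared per-variable
variances:

* `Y_PKRES` — individually weighted residuals,
  `IWRES = (DV − IPRED) / (σ·IPRED)`, from a one-compartment population PK
  model fitted to first-dosing-occasion data only (drug-naive, hence
  ADA-free) and extrapolated to all later occasions. ADA-driven clearance
  increases make the model over-predict, so these residuals drift negative.
* `Y_ADA` — the ADA measurement (U/mL; LLOQ 0.6, clinical threshold 2.4).

The subject likelihood is the scaled forward recursion (record 1 evaluated
under `S_NOADA` alone; per-record normalization); subject-level random
effects on modes and transition logits, where a model variant activates
them, are integrated out by Gauss–Hermite quadrature. Six variants cover
{ADA modes estimated vs fixed at 0.6/2.4} × {IIV on modes + transitions,
transitions only, none}; variant 6 (fixed modes, no IIV) is the default.
After fitting, per-subject state sequences are decoded with the Viterbi
algorithm and compared against the threshold-based clinical classification.

A trial-faithful cohort simulator (dose-ranging Q4W, Q2W with loading
doses, a single-dose phase-I study without ADA sampling) makes the whole
pipeline testable end to end; the methods vignette
(`vignettes/ada-mhmm-methods.Rmd`) documents the model, its assumptions and
its limitations.

## Worked example

Simulate a 300-subject cohort across the default trial designs, fit the PK
stage, build the bivariate records, fit variant 6 and compare decoded state
sequences with the clinical classification (a few minutes, single core):

```r
library(adamhmm)

coh <- simulate_cohort(default_designs(300), seed = 1)
ds  <- as_ada_dataset(coh$data)

pkfit <- fit_first_occasion(ds, default_pk_params(),
                            fixed = c("ka", "theta_wt_cl",
                                      "theta_jp_cl", "theta_jp_v"))
ebes <- compute_ebes(pkfit, ds)
iw   <- compute_iwres(pkfit, ebes, ds)

rec <- prepare_hmm_records(ds, iw)
fit <- fit_mhmm(rec, variant_config(6), seed = 1, n_multistart = 2, se = TRUE)
fit
#> Mixed hidden-Markov model fit (variant 6)
#> log-likelihood: -5765.8436  converged: TRUE
#> mu_pkres_noada   mu_pkres_ada   sigma2_pkres     sigma2_ada      rho_noada
#>        0.35656       -2.54897        2.99951        0.08892       -0.00345
#>        rho_ada           pi12           pi21
#>       -0.00924        0.03044        0.00582

decoded <- decode_states(rec, fit)
clin    <- classify_clinical(coh$data)
compare_times(clin, summarize_paths(decoded))
#> Clinically positive subjects paired: 56
#> mean time to first positive measurement: 66.5 days
#> mean decoded first time in S_ADA:        55.1 days
```

Reading the output: the residual mode in `S_NOADA` is near zero and clearly
negative in `S_ADA` (the PK over-prediction signal); `pi12 ≈ 0.030`
recovers the generating per-record entry probability (0.03), and `pi21` is
small — ADA production, once started, rarely stops. The decoded state
sequences place ADA onset on average ~11 days before the first
above-threshold measurement: the model flags production before the assay
confirms it. Against the simulator's stored hidden truth, the decoded
ever-in-`S_ADA` flag reaches a balanced accuracy of 0.99 here.

A thin command-line interface wraps the same functions
(`inst/cli/adamhmm`, subcommands `simulate`, `pkfit`, `residuals`, `fit`,
`decode`, `evaluate`, `ppc`).

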