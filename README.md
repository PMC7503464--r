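# relaxkin

Analysis of laser temperature-jump (T-jump) fluorescence relaxation
experiments on ligand-binding enzymes, written for protein biophysicists
studying binding kinetics and conformational dynamics through intrinsic
tryptophan fluorescence — the canonical use case being single-tryptophan
dihydrofolate reductase (DHFR) mutants relaxing after a 29 → 36 °C jump
in the presence of folate.

## The method

A T-jump perturbs a binding equilibrium; the return to equilibrium is
biphasic. For two-state binding
`E + L <=> EL` (rate constants `k_on`, `k_off`), the fast relaxation
rate is linear in the sum of free concentrations evaluated at the
post-jump temperature:

    k_fast = k_on ([E]_free + [L]_free) + k_off

so an ordinary least-squares line through `k_fast` versus
`[E]_free + [L]_free` yields `k_on` (slope), `k_off` (intercept) and a
kinetic dissociation constant `Kd = k_off / k_on`. A second, slower
phase that does not move with concentration reports a unimolecular
conformational change and is summarized by its pooled mean and standard
deviation. Whether a phase "moves with concentration" is decided by the
Pearson coefficient `r` against critical values from the two-tailed
t distribution, `r_crit = t_c / sqrt(t_c^2 + DF)` with `DF = n - 2`
(0.505 / 0.337 / 0.265 at the 99% / 90% / 80% levels for `DF = 23`).
Negative `r` is always classified independent — a rate cannot
physically fall with concentration.

Around this core the package provides: a seeded forward simulator of
the full experimental design (transient ladders, free-Trp reference,
emission spectra, CD melts, activity traces); preprocessing (reference
subtraction, normalization to percent change); double-exponential
fitting with automatic initialization; the van 't Hoff projection of a
calorimetric Kd to the post-jump temperature with an exact, numerically
stable free-concentration solver; and the equilibrium-side workflow
(band integration, percent-of-apoenzyme tables, 4-parameter-logistic
melt fits for Tm, relative activity from initial rates).

## Worked example

Simulate the wild-type-anchored design (100 µM enzyme, five folate
concentrations up to 200 µM, five replicates, 1% noise) and run the full
estimator:

```r
library(relaxkin)

sc  <- kinetic_scenario(seed = 7)   # defaults encode the study design
res <- tjump_kinetics(simulate(sc))
res
#> T-jump relaxation kinetics: enzyme (25 transients, 25 converged)
#>   fast phase: r = 0.973 -> dependent
#>   slow phase: r = -0.040 -> independent
#>   k_on  = 32.2 +/- 1.6 uM-1 s-1
#>   k_off = 1086 +/- 127 s-1
#>   Kd (kinetic) = 33.7 uM vs Kd (ITC) = 4.7 uM (ratio 7.2)
#>   slow rate: 410.9 +/- 48 s-1 (n = 25)
```

The generating constants were `k_on = 31` µM⁻¹s⁻¹, `k_off = 1100` s⁻¹
and `k_slow = 400` s⁻¹: the fast phase is correctly classified as
concentration dependent (ligand binding), the slow phase as independent
(a conformational event), and all three constants are recovered within
their standard errors. The kinetic Kd exceeding the calorimetric Kd —
here by a factor of ~7 — is the hallmark that the fast phase is binding
*convolved with* an associated conformational change rather than pure
association/dissociation.

Individual pieces are usable on their own:

```r
classify_dependence(0.366, 25)
#> Concentration-dependence test: r = 0.366 (n = 25, DF = 23) -> weakly_dependent
#>   critical r: 0.505 @ 99%, 0.337 @ 90%, 0.265 @ 80%

fit_melt(generate_melt_curve(Tm = 48, noise_sd = 0.2, seed = 7))
#> CD thermal melt fit (4-parameter logistic):
#>   Tm = 48.05 +/- 0.24 C, width = 2.49 C
#>   baselines: folded -12, unfolded -1.77; RMS 0.223; converged: TRUE
```

File-based pipelines (`run_simulate()`, `run_fit_transients()`,
`run_analyze()`, `run_equilibrium()`) read and write plain CSV with a
manifest, ground-truth sidecars and human-readable reports; see the
vignette (`vignettes/relaxation-kinetics.Rmd`) for the model details,
parameter choices and limitations.

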