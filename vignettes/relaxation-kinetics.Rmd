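---
title: "Temperature-jump relaxation kinetics with relaxkin"
author: "relaxkin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-jump relaxation kinetics with relaxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(relaxkin)
```

## The experiment and the model

A laser temperature jump (T-jump) heats an equilibrated enzyme–ligand
sample by a few degrees in nanoseconds and watches the system relax to
the new equilibrium through a fluorescent probe — here the intrinsic
tryptophan emission of dihydrofolate reductase (DHFR) mutants carrying a
single tryptophan. Because a T-jump perturbs an equilibrium rather than
mixing reactants, the observed relaxation carries information about the
forward *and* reverse reactions.

For a two-state binding equilibrium

$$E + L \underset{k_{\mathrm{off}}}{\overset{k_{\mathrm{on}}}{\rightleftharpoons}} EL,$$

linearizing the rate equation about the post-jump equilibrium gives a
single relaxation mode with rate

$$k_{\mathrm{fast}} = k_{\mathrm{on}}\,([E]_{\mathrm{free}} +
[L]_{\mathrm{free}}) + k_{\mathrm{off}},$$

so the fast rate is *linear in the sum of free concentrations*: the slope
of that line is $k_{\mathrm{on}}$, the intercept is $k_{\mathrm{off}}$,
and their ratio $k_{\mathrm{off}}/k_{\mathrm{on}}$ is a kinetic estimate
of the dissociation constant. A second, slower relaxation that does
*not* move with concentration is a unimolecular event — a conformational
change — and is summarized by pooling all fitted slow rates. This
two-phase picture, and the classification of phases by their
concentration dependence, is what the package implements end to end.

The measured transients are percent-change fluorescence signals

$$F(t) = \mathrm{baseline} + a_{\mathrm{fast}}\,(1 - e^{-k_{\mathrm{fast}}t})
       + a_{\mathrm{slow}}\,(1 - e^{-k_{\mathrm{slow}}t}),$$

with rising saturating exponentials because ligand dissociation upon
heating increases the tryptophan emission; the amplitudes are signed, so
decaying phases are equally representable.

## Free concentrations at the post-jump temperature

The concentration axis of the rate plot must be evaluated *after* the
jump. The dissociation constant measured calorimetrically at a reference
temperature is projected with the integrated van 't Hoff relation on the
association constant $K_a = 1/K_d$ (constant binding enthalpy
$\Delta H$):

$$\ln K_a(T_2) - \ln K_a(T_1) = -\frac{\Delta H}{R}\left(\frac{1}{T_2} -
\frac{1}{T_1}\right).$$

An exothermic complex ($\Delta H < 0$) therefore binds more weakly when
heated, which is also why the jump produces net dissociation and a
fluorescence rise. An optional $\Delta C_p$ term is available but off by
default: the minimal model matches what the calorimetric inputs
constrain. The published per-mutant binding enthalpies are not
available, so the default $\Delta H = -10$ kcal/mol (at a 25 °C
reference) is a documented placeholder of typical magnitude for
folate–DHFR association, to be replaced by the user's own ITC numbers
for real analyses.

Bound complex concentrations come from the exact quadratic solution of
the mass-action equation, computed through the product form of the
smaller root,

$$[EL] = \frac{2\,E_t L_t}{\,b + \sqrt{b^2 - 4E_tL_t}\,},\qquad
b = E_t + L_t + K_d,$$

which avoids catastrophic cancellation in the tight-binding regime
($K_d \ll$ totals); tests verify agreement with a numeric root search to
$10^{-9}$ relative over wide random ranges.

```{r}
bp <- binding_parameters(kd_ref = 4.7, delta_H = -10, T_ref = 298.15)
adjust_kd(bp, 309.15)          # Kd at 36 C
free_concentrations(100, 50, adjust_kd(bp, 309.15))
```

## What the simulator emulates — and what it does not

`kinetic_scenario()` encodes the full study design as its defaults: 100
µM enzyme, five folate concentrations (25–200 µM) each measured in five
replicates ($n = 25$), a 29 → 36 °C jump, wild-type-anchored rate
constants ($k_{\mathrm{on}} = 31$ µM⁻¹s⁻¹, $k_{\mathrm{off}} = 1100$
s⁻¹, $k_{\mathrm{slow}} = 400$ s⁻¹), an intrinsic free-tryptophan
background that steps down by 7% at the jump (≈ −1% per °C), and 1%
i.i.d. Gaussian noise per point. The time base is 1000 logarithmically
spaced points from 1 µs to 10 ms — resolving rates from roughly $10^2$
to $10^6$ s⁻¹ — preceded by 64 pre-jump baseline points that define the
initial intensity for normalization.

Two generator choices deserve explanation:

* **Phase amplitudes** (12% and 8% of the pre-jump intensity for the
  fast and slow phase) are not published anywhere. They were fixed once
  by an identifiability analysis: the Cramér–Rao bound for this grid and
  noise level shows they are close to the smallest round values at which
  both rates remain resolvable per single transient (expected median
  rate errors ≈ 3% and 8%), which is the regime the replicated $n = 25$
  design presupposes. Smaller amplitudes make individual transients
  uninformative about the slow rate no matter the fitter.
* **Noise** is i.i.d. Gaussian per point. Real detectors add correlated
  (1/f, shot) components and the instrument response convolves the first
  microseconds; neither is modelled, so passing recovery tests here
  demonstrates correctness of the estimator, not robustness to every
  instrumental artefact.

The scenario constructor refuses designs in which any realized fast rate
comes within a factor of two of the slow rate, since the two phases
would not be separable by any fitter.

## Preprocessing: reference subtraction and normalization

Free tryptophan fluorescence falls with temperature, so each enzyme
transient rides on a non-kinetic step. A free-Trp reference transient is
resampled onto the sample grid, scaled by the ratio of pre-jump
intensities $s$, and its *change about its own pre-jump level* is
subtracted:

$$F_{\mathrm{corr}}(t) = F(t) - s\,\bigl(F_{\mathrm{ref}}(t) -
\bar F_{\mathrm{ref}}^{\,\mathrm{pre}}\bigr).$$

Centring the reference is a deliberate choice: subtracting the full
scaled reference would null the pre-jump level and make the subsequent
normalization ("divide the whole trace by its initial intensity, times
100") ill-defined. The centred form removes exactly the intrinsic
temperature response while preserving the sample's pre-jump intensity;
the literal uncentred subtraction remains available via
`center = FALSE`, and the applied scale is recorded in the output
metadata. The normalization window is the pre-jump segment when one
exists, otherwise the first 1% of points (configurable) — early enough
that the kinetic phases have not evolved.

```{r}
sc <- kinetic_scenario(seed = 7)
tr <- generate_transient(sc, ligand_total = 200)
ref <- generate_reference_transient(sc)
norm <- normalize_transient(subtract_reference(tr, ref))
fit <- fit_double_exponential(norm)
fit
plot(fit)
```

## Fitting choices

Each corrected, normalized transient is fit by unweighted nonlinear
least squares (no per-point uncertainties are available to weight by)
with a floated baseline. Starting values need no user input: a coarse
separable search evaluates log-spaced rate pairs, solving the amplitudes
and baseline linearly at each pair (variable projection), and the best
pair seeds a Levenberg–Marquardt refinement. This is more robust than
sequential tail "peeling" when the phases overlap, at negligible cost.
Rates are constrained positive, reported sorted
($k_{\mathrm{fast}} \ge k_{\mathrm{slow}}$), and carry standard errors
from the fit covariance. Degenerate inputs are flagged rather than
silently reported: a rate ratio below 1.5 raises an identifiability
warning (a noiseless single-exponential input, for example, legitimately
collapses both rates onto the true one and splits the amplitude), a
window shorter than $3/k_{\mathrm{slow}}$ raises a coverage warning, and
optimizer failure returns `converged = FALSE`.

## Classification and extraction

The strength of the concentration dependence of each phase is the
Pearson coefficient $r$ between the fitted rates and the sum of free
concentrations, judged against critical values from the two-tailed
$t$ distribution,

$$r_{\mathrm{crit}} = \frac{t_c}{\sqrt{t_c^2 + \mathrm{DF}}},\qquad
\mathrm{DF} = n - 2,$$

which at $\mathrm{DF} = 23$ gives 0.505, 0.337 and 0.265 at the 99%,
90% and 80% confidence levels (the two-tailed quantile reproduces all
three printed thresholds; a one-tailed quantile does not). A phase is
"dependent" at the 99% level, "weakly dependent" at the 90% level, and
"independent" otherwise; a *negative* $r$ is always classified
independent, since a relaxation rate cannot physically decrease with
concentration. When the fast phase itself classifies as independent,
`tjump_kinetics()` withholds $k_{\mathrm{on}}$, $k_{\mathrm{off}}$ and
the kinetic $K_d$ entirely — a slope through concentration-independent
rates estimates nothing.

```{r}
res <- tjump_kinetics(simulate(sc))
res
plot(res, "fast")
```

Pooled slow statistics use the sample ($n-1$) standard deviation; the
published ± convention is unspecified, and this is the conservative
reading. Note one honest caveat: with 25 fits, the correlation
coefficient of a genuinely concentration-independent phase has a
sampling standard deviation near 0.2, so roughly one experiment in
twenty will show $|r|$ above the 90% threshold by chance alone. The
package's acceptance summary therefore evaluates the recovery surface as
means over 20 repeated experiments.

## Equilibrium characterization

The equilibrium side mirrors the standard workflow:

* **Band integration** — trapezoidal quadrature with linear
  interpolation at the band edges; the default 327–353 nm band matches
  the detection bandpass filter. Complex spectra are reported as
  percentages of the apoenzyme integral.
* **Temperature series** — integrated intensities are normalized to the
  lowest temperature and the normalized free-Trp reference is
  subtracted, yielding a change-in-intensity series that is zero at the
  grid start. The alternative subtract-then-normalize order is
  implemented behind a flag (`order = "subtract_first"`) because the
  original arithmetic is not published; the applied order is recorded on
  the output.
* **Thermal melts** — ellipticity at 222 nm versus temperature is fit to
  a four-parameter logistic (two baselines, midpoint $T_m$, width); "a
  sigmoid" is all the protocol specifies, and the 4PL is its simplest
  faithful form. A fit whose baseline separation is indistinguishable
  from noise, or whose midpoint pins to the edge of the measured range,
  is flagged non-convergent.
* **Relative activity** — initial rates are OLS slopes over the early
  window of the A340 trace (default: first 10% of points), reported as a
  percentage of the wild-type rate.

```{r}
sp <- midw_spectral_scenario("midW22", seed = 7)
apo <- integrate_full_peak(generate_spectrum(sp, "apo"))
round(sapply(c("E.NADP", "E.Folate", "E.NADP.Folate"), function(lab)
  percent_of_apo(integrate_full_peak(generate_spectrum(sp, lab)), apo)), 1)
fit_melt(generate_melt_curve(Tm = 48, noise_sd = 0.2, seed = 7))
```

## Problem sizes, tolerances and limitations

The shipped tests and the acceptance summary run the design at its
native size — 25 transients of 1064 points per experiment, 20
repetitions for the recovery surface, 1000 random instances for the
equilibrium-solver cross-check, and 100 noisy repeats for the melt
recovery property — all generated in code from fixed seeds. Numerical
tolerances worth knowing: the mass-action solver is verified to
$10^{-9}$ relative; noiseless transient fits recover rates to well below
0.1%; noiseless melt fits recover $T_m$ to 0.1 °C.

Known limitations: no instrument response function (the reference step
is instantaneous), no multi-curve global fitting (the procedure is
per-transient fits followed by regression, by design), no stretched
exponentials or rate distributions, no $\Delta C_p$ by default, and no
photophysics (excimer formation, FRET) in the spectral model. The
per-mutant binding enthalpies and the exact published noise levels are
unknown; where they matter, the defaults are documented choices, not
measurements.
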