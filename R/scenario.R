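## Scenario descriptions for the synthetic-data generators. The kinetic
## scenario encodes the full T-jump experimental design: one enzyme at a
## fixed total concentration, a ladder of ligand concentrations measured
## in replicate, a 29 -> 36 C jump, and the two-phase relaxation model
##   F(t) = F0 [ 1 + a_fast (1 - e^{-k_fast t}) + a_slow (1 - e^{-k_slow t}) ]
## with k_fast = k_on (E_free + L_free) + k_off evaluated at the post-jump
## temperature.

#' Scenario for simulating a T-jump binding-kinetics experiment
#'
#' Describes the experimental design and ground-truth kinetics from which
#' synthetic T-jump fluorescence transients are generated. The defaults
#' reproduce the wild-type DHFR-folate design: 100 uM enzyme, five folate
#' concentrations up to 200 uM measured in five replicates, a 29 to 36 C
#' jump, `k_on` = 31 uM-1 s-1, `k_off` = 1100 s-1, a concentration-
#' independent slow phase at 400 s-1, and 1% Gaussian noise. The default
#' phase amplitudes (12% and 8% of the pre-jump intensity) were fixed by
#' an identifiability analysis: they are the smallest round values at
#' which both rates stay resolvable on this grid at 1% noise (see the
#' package vignette).
#'
#' @param k_on Association rate constant (uM-1 s-1), > 0.
#' @param k_off Dissociation rate constant (s-1), >= 0.
#' @param k_slow Concentration-independent slow relaxation rate (s-1), > 0.
#'   Must be separated from every realized fast rate by at least
#'   `separation` so the two phases are resolvable.
#' @param amp_fast,amp_slow Fractional fluorescence amplitudes of the two
#'   phases (signed; positive = intensity rises after the jump).
#' @param enzyme_total Total enzyme concentration (uM).
#' @param ligand_totals Vector of total ligand concentrations (uM),
#'   non-negative, at least 3 distinct values.
#' @param replicates Replicates per concentration.
#' @param t_start,t_end,n_points Post-jump time grid: `n_points`
#'   logarithmically spaced times from `t_start` to `t_end` (s).
#' @param n_pre,t_pre Pre-jump baseline: `n_pre` linearly spaced points on
#'   `[-t_pre, 0)` (s). Set `n_pre = 0` for a post-jump-only grid.
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   pre-jump intensity.
#' @param bg_step Fractional instantaneous step of the intrinsic
#'   tryptophan background after the jump (negative: free-Trp
#'   fluorescence decreases with temperature; default -7%, about -1% per
#'   degree over the 7 C jump).
#' @param ref_noise_sd Fractional noise of the free-Trp reference
#'   transient (brighter sample, lower relative noise).
#' @param T_initial,T_final Pre-/post-jump temperatures (C).
#' @param binding A [binding_parameters()] object used to compute free
#'   concentrations at `T_final`. The default anchors the ITC Kd of the
#'   wild-type DHFR-folate complex (4.7 uM) at 25 C with a placeholder
#'   enthalpy of -10 kcal/mol (the per-enzyme ITC enthalpies are not
#'   published; supply your own for real work).
#' @param separation Minimum required ratio between every realized fast
#'   rate and `k_slow` (default 2).
#' @param f0 Pre-jump sample intensity (arbitrary units).
#' @param seed Base seed from which per-transient seeds are derived.
#' @return An object of class `"kinetic_scenario"`.
#' @examples
#' sc <- kinetic_scenario(noise_sd = 0)
#' tr <- generate_transient(sc, ligand_total = 200)
#' @export
kinetic_scenario <- function(k_on = 31, k_off = 1100, k_slow = 400,
                             amp_fast = 0.12, amp_slow = 0.08,
                             enzyme_total = 100,
                             ligand_totals = c(25, 50, 100, 150, 200),
                             replicates = 5L,
                             t_start = 1e-6, t_end = 1e-2, n_points = 1000L,
                             n_pre = 64L, t_pre = 5e-4,
                             noise_sd = 0.01, bg_step = -0.07,
                             ref_noise_sd = noise_sd / 5,
                             T_initial = 29, T_final = 36,
                             binding = binding_parameters(4.7, -10, 298.15),
                             separation = 2, f0 = 1, seed = 1L) {
  stopifnot(is.numeric(ligand_totals), length(ligand_totals) >= 1L)
  if (k_on <= 0) stop("'k_on' must be > 0")
  if (k_off < 0) stop("'k_off' must be >= 0")
  if (k_slow <= 0) stop("'k_slow' must be > 0")
  if (any(ligand_totals < 0)) stop("'ligand_totals' must be non-negative")
  if (length(unique(ligand_totals)) < 3L)
    stop("need at least 3 distinct ligand concentrations")
  if (t_start <= 0 || t_end <= t_start)
    stop("need 0 < t_start < t_end")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (f0 <= 0) stop("initial intensity 'f0' must be positive")
  sc <- structure(list(k_on = k_on, k_off = k_off, k_slow = k_slow,
                       amp_fast = amp_fast, amp_slow = amp_slow,
                       enzyme_total = enzyme_total,
                       ligand_totals = ligand_totals,
                       replicates = as.integer(replicates),
                       t_start = t_start, t_end = t_end,
                       n_points = as.integer(n_points),
                       n_pre = as.integer(n_pre), t_pre = t_pre,
                       noise_sd = noise_sd, bg_step = bg_step,
                       ref_noise_sd = ref_noise_sd,
                       T_initial = T_initial, T_final = T_final,
                       binding = binding, separation = separation,
                       f0 = f0, seed = as.integer(seed)),
                  class = "kinetic_scenario")
  ## phase resolvability: every realized fast rate must clear k_slow
  kf <- true_fast_rates(sc)
  if (any(kf < separation * k_slow))
    stop(sprintf(
      "slow rate %.3g s-1 is not separated from the fast rates (min %.3g s-1) by a factor of %.3g",
      k_slow, min(kf), separation))
  sc
}

#' @export
print.kinetic_scenario <- function(x, ...) {
  cat("T-jump kinetic scenario:\n")
  cat(sprintf("  k_on %.3g uM-1 s-1, k_off %.3g s-1, k_slow %.3g s-1\n",
              x$k_on, x$k_off, x$k_slow))
  cat(sprintf("  %.4g uM enzyme; ligand %s uM x %d replicates\n",
              x$enzyme_total, paste(x$ligand_totals, collapse = "/"),
              x$replicates))
  cat(sprintf("  jump %.1f -> %.1f C; noise %.2g%%; seed %d\n",
              x$T_initial, x$T_final, 100 * x$noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth fast relaxation rates of a scenario
#'
#' The fast phase of a two-state binding relaxation obeys
#' `k_fast = k_on (E_free + L_free) + k_off`, with the free concentrations
#' evaluated at the post-jump temperature.
#'
#' @param scenario A [kinetic_scenario()].
#' @param ligand_totals Ligand concentrations (uM); defaults to the
#'   scenario's ladder.
#' @return Vector of fast relaxation rates (s-1).
#' @export
true_fast_rates <- function(scenario, ligand_totals = scenario$ligand_totals) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  Tk <- scenario$T_final + 273.15
  sf <- vapply(ligand_totals, function(L)
    sum_free_at(scenario$binding, scenario$enzyme_total, L, Tk), numeric(1))
  scenario$k_on * sf + scenario$k_off
}

#' Scenario for simulating tryptophan emission spectra
#'
#' One enzyme's tryptophan emission is modelled as a Gaussian band; each
#' enzyme-ligand complex scales the apoenzyme band by a quench factor, so
#' integrated intensities expressed as a percentage of the apoenzyme
#' reproduce configured quenching tables.
#'
#' @param center Emission band center (nm).
#' @param bandwidth Gaussian standard deviation (nm).
#' @param amplitude Apoenzyme peak amplitude (arbitrary units), > 0.
#' @param quench Named vector of per-complex quench factors in (0, 1.2];
#'   must include `"apo"` (normally 1).
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param noise_sd Gaussian noise, as a fraction of the apo peak amplitude.
#' @param enzyme Label for the enzyme.
#' @param seed Integer seed.
#' @return An object of class `"spectral_scenario"`.
#' @export
spectral_scenario <- function(center = 340, bandwidth = 18, amplitude = 100,
                              quench = c(apo = 1),
                              wavelength = seq(300, 420, by = 1),
                              noise_sd = 0.005, enzyme = "enzyme",
                              seed = 1L) {
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  if (is.null(names(quench)) || any(!nzchar(names(quench))))
    stop("'quench' must be a named vector of complex labels")
  if (any(quench <= 0 | quench > 1.2))
    stop("quench factors must lie in (0, 1.2]")
  if (any(diff(wavelength) <= 0))
    stop("'wavelength' must be strictly increasing")
  if (bandwidth <= 0) stop("'bandwidth' must be > 0")
  structure(list(center = center, bandwidth = bandwidth,
                 amplitude = amplitude, quench = quench,
                 wavelength = wavelength, noise_sd = noise_sd,
                 enzyme = enzyme, seed = as.integer(seed)),
            class = "spectral_scenario")
}

#' @export
print.spectral_scenario <- function(x, ...) {
  cat(sprintf("Spectral scenario '%s': band %.0f nm (sd %.0f), peak %.3g\n",
              x$enzyme, x$center, x$bandwidth, x$amplitude))
  cat("  quench factors:",
      paste(sprintf("%s %.2f", names(x$quench), x$quench), collapse = ", "),
      "\n")
  invisible(x)
}

## Default emission-band parameters for the five single-Trp DHFR mutants.
## Peak amplitudes ordered W74 > W30 > W47 > W133 > W22; W47/W133 bands
## blue-shifted relative to W22/W30/W74. Quench factors are configured so
## that integrated percent-of-apo values reproduce the measured table for
## E.NADP, E.Folate and E.NADP.Folate complexes.
.midw_bands <- list(
  midW22  = list(center = 341, amplitude = 15,
                 quench = c(apo = 1, E.NADP = 1.02, E.Folate = 0.52,
                            E.NADP.Folate = 0.49)),
  midW30  = list(center = 342, amplitude = 80,
                 quench = c(apo = 1, E.NADP = 1.06, E.Folate = 0.42,
                            E.NADP.Folate = 0.40)),
  midW47  = list(center = 332, amplitude = 55,
                 quench = c(apo = 1, E.NADP = 0.92, E.Folate = 0.71,
                            E.NADP.Folate = 0.54)),
  midW74  = list(center = 340, amplitude = 100,
                 quench = c(apo = 1, E.NADP = 0.98, E.Folate = 0.64,
                            E.NADP.Folate = 0.61)),
  midW133 = list(center = 334, amplitude = 40,
                 quench = c(apo = 1, E.NADP = 0.93, E.Folate = 0.64,
                            E.NADP.Folate = 0.63)))

#' Preset spectral scenario for a single-tryptophan DHFR mutant
#'
#' @param mutant One of `"midW22"`, `"midW30"`, `"midW47"`, `"midW74"`,
#'   `"midW133"`.
#' @param ... Overrides passed to [spectral_scenario()].
#' @return A [spectral_scenario()] with the mutant's preset band center,
#'   amplitude and per-complex quench factors.
#' @export
midw_spectral_scenario <- function(mutant = c("midW22", "midW30", "midW47",
                                              "midW74", "midW133"), ...) {
  mutant <- match.arg(mutant)
  b <- .midw_bands[[mutant]]
  args <- list(center = b$center, amplitude = b$amplitude,
               quench = b$quench, enzyme = mutant)
  args[names(list(...))] <- list(...)
  do.call(spectral_scenario, args)
}
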