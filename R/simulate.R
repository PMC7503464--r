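## Forward models generating every input the analysis consumes:
## T-jump transients and the free-Trp reference, emission spectra,
## CD thermal melt curves and activity traces. All randomness is seeded
## and isolated from the caller's RNG state.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Shared time grid: optional pre-jump baseline then log-spaced post-jump.
.scenario_grid <- function(sc) {
  post <- exp(seq(log(sc$t_start), log(sc$t_end), length.out = sc$n_points))
  if (sc$n_pre > 0L) {
    pre <- seq(-sc$t_pre, -sc$t_start / 2, length.out = sc$n_pre)
    c(pre, post)
  } else post
}

#' Simulate one T-jump fluorescence transient
#'
#' Evaluates the two-phase relaxation forward model on the scenario's time
#' grid. For post-jump times,
#' `F(t) = F0 [1 + a_fast (1 - e^(-k_fast t)) + a_slow (1 - e^(-k_slow t)) + bg_step]`
#' with `k_fast = k_on (E_free + L_free) + k_off`, the free concentrations
#' taken at the post-jump temperature from the scenario's binding
#' parameters; pre-jump times sit at `F0`. Gaussian noise with standard
#' deviation `noise_sd * F0` is added per point. The ground-truth rates
#' are recorded in the result's `meta` for recovery tests.
#'
#' @param scenario A [kinetic_scenario()].
#' @param ligand_total Total ligand concentration (uM) of this sample.
#' @param replicate Replicate index (bookkeeping).
#' @param replicate_seed Seed for this transient's noise (default derived
#'   from the scenario seed).
#' @return A [transient_record()].
#' @export
generate_transient <- function(scenario, ligand_total,
                               replicate = 1L, replicate_seed = NULL) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  if (ligand_total < 0) stop("'ligand_total' must be >= 0")
  if (is.null(replicate_seed)) replicate_seed <- scenario$seed
  t <- .scenario_grid(scenario)
  k_fast <- true_fast_rates(scenario, ligand_total)
  post <- t > 0
  f <- rep(1, length(t))
  f[post] <- 1 +
    scenario$amp_fast * (1 - exp(-k_fast * t[post])) +
    scenario$amp_slow * (1 - exp(-scenario$k_slow * t[post])) +
    scenario$bg_step
  f <- scenario$f0 * f
  if (scenario$noise_sd > 0)
    f <- .with_seed(replicate_seed,
                    f + stats::rnorm(length(f),
                                     sd = scenario$noise_sd * scenario$f0))
  transient_record(
    time = t, intensity = f,
    enzyme_total = scenario$enzyme_total, ligand_total = ligand_total,
    T_initial = scenario$T_initial, T_final = scenario$T_final,
    replicate = replicate,
    label = sprintf("L%.4g_r%d", ligand_total, replicate),
    meta = list(truth = list(k_fast = k_fast, k_slow = scenario$k_slow,
                             amp_fast = scenario$amp_fast,
                             amp_slow = scenario$amp_slow,
                             bg_step = scenario$bg_step,
                             f0 = scenario$f0),
                seed = replicate_seed))
}

#' Simulate the free-tryptophan reference transient
#'
#' Free tryptophan has no binding or conformational kinetics; its
#' fluorescence simply steps down when the temperature rises (the
#' intrinsic temperature dependence of Trp emission). The step is modelled
#' as instantaneous on the kinetic window.
#'
#' @param scenario A [kinetic_scenario()].
#' @param intensity Pre-jump reference intensity (arbitrary units); the
#'   free-Trp reference is typically much brighter than the enzyme sample.
#' @param seed Seed for the reference noise.
#' @return A [transient_record()] labelled `"trp_reference"`.
#' @export
generate_reference_transient <- function(scenario, intensity = 5 * scenario$f0,
                                         seed = scenario$seed + 999L) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  t <- .scenario_grid(scenario)
  f <- intensity * (1 + scenario$bg_step * (t > 0))
  if (scenario$ref_noise_sd > 0)
    f <- .with_seed(seed,
                    f + stats::rnorm(length(f),
                                     sd = scenario$ref_noise_sd * intensity))
  transient_record(
    time = t, intensity = f,
    enzyme_total = 0, ligand_total = 0,
    T_initial = scenario$T_initial, T_final = scenario$T_final,
    replicate = 1L, label = "trp_reference",
    meta = list(truth = list(bg_step = scenario$bg_step, f0 = intensity)))
}

#' Simulate a full T-jump experiment
#'
#' Generates every transient of the scenario's design (each ligand
#' concentration in each replicate) plus the free-Trp reference, with
#' per-transient seeds derived deterministically from the scenario seed.
#'
#' @param object A [kinetic_scenario()].
#' @param nsim Unused (one experiment per call), kept for the generic.
#' @param seed Optional override of the scenario seed.
#' @param ... Ignored.
#' @return A list of class `"tjump_experiment"` with elements
#'   `transients` (list of [transient_record()]), `reference`, `truth`
#'   (data frame of ground-truth rates per sample) and `scenario`.
#' @export
simulate.kinetic_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  sc <- object
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  idx <- 0L
  transients <- list()
  truth <- list()
  for (ci in seq_along(sc$ligand_totals)) {
    L <- sc$ligand_totals[ci]
    for (r in seq_len(sc$replicates)) {
      idx <- idx + 1L
      tr <- generate_transient(sc, L, replicate = r,
                               replicate_seed = sc$seed + 131L * idx)
      transients[[idx]] <- tr
      truth[[idx]] <- data.frame(sample_id = tr$label, ligand_uM = L,
                                 replicate = r,
                                 k_fast = tr$meta$truth$k_fast,
                                 k_slow = tr$meta$truth$k_slow)
    }
  }
  structure(list(transients = transients,
                 reference = generate_reference_transient(sc),
                 truth = do.call(rbind, truth),
                 scenario = sc),
            class = "tjump_experiment")
}

#' @export
print.tjump_experiment <- function(x, ...) {
  cat(sprintf("Simulated T-jump experiment: %d transients (%d concentrations x %d replicates) + reference\n",
              length(x$transients), length(x$scenario$ligand_totals),
              x$scenario$replicates))
  invisible(x)
}

#' Simulate a tryptophan emission spectrum
#'
#' Gaussian emission band on the scenario's wavelength grid, scaled by the
#' complex's quench factor, plus Gaussian noise.
#'
#' @param scenario A [spectral_scenario()].
#' @param label Complex label; must be one of `names(scenario$quench)`.
#' @param seed Optional seed override.
#' @return A [spectrum_record()].
#' @export
generate_spectrum <- function(scenario, label = "apo", seed = NULL) {
  stopifnot(inherits(scenario, "spectral_scenario"))
  if (!label %in% names(scenario$quench))
    stop(sprintf("unknown complex label '%s'", label))
  if (is.null(seed)) seed <- scenario$seed + match(label, names(scenario$quench))
  wl <- scenario$wavelength
  q <- scenario$quench[[label]]
  y <- q * scenario$amplitude *
    exp(-(wl - scenario$center)^2 / (2 * scenario$bandwidth^2))
  if (scenario$noise_sd > 0)
    y <- .with_seed(seed,
                    y + stats::rnorm(length(y),
                                     sd = scenario$noise_sd * scenario$amplitude))
  spectrum_record(wl, y, complex_label = label, enzyme = scenario$enzyme)
}

#' Simulate a CD thermal melt curve
#'
#' Sigmoidal loss of ellipticity at 222 nm with temperature, sampled by
#' default every 5 C from 10 to 90 C. The noiseless curve passes exactly
#' through the midpoint of the two baselines at `T = Tm`.
#'
#' @param Tm Melting temperature (C).
#' @param width Transition width (C), > 0.
#' @param baselines Length-2 vector `c(folded, unfolded)` ellipticities
#'   (mdeg; folded is the more negative at 222 nm).
#' @param noise_sd Gaussian noise (mdeg).
#' @param seed Integer seed.
#' @param temperatures Temperature grid (C).
#' @return Data frame with columns `temperature_C`, `ellipticity`.
#' @export
generate_melt_curve <- function(Tm = 48, width = 2.5,
                                baselines = c(-12, -2), noise_sd = 0,
                                seed = 1L,
                                temperatures = seq(10, 90, by = 5)) {
  if (width <= 0) stop("'width' must be > 0")
  folded <- baselines[1]
  unfolded <- baselines[2]
  frac_unfolded <- 1 / (1 + exp(-(temperatures - Tm) / width))
  y <- folded + (unfolded - folded) * frac_unfolded
  if (noise_sd > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  data.frame(temperature_C = temperatures, ellipticity = y)
}

#' Simulate an enzyme activity trace (A340 vs time)
#'
#' NADPH oxidation is followed by the disappearance of its 340 nm
#' absorbance band; the initial rate is the early-time slope. The trace is
#' a gentle exponential decay whose slope at `t = 0` equals
#' `-initial_rate`.
#'
#' @param initial_rate Initial rate (absorbance units per second), >= 0.
#' @param duration Trace length (s).
#' @param dt Sampling interval (s).
#' @param A0 Starting absorbance.
#' @param A_inf Final absorbance once substrate is exhausted.
#' @param noise_sd Gaussian noise (absorbance units).
#' @param seed Integer seed.
#' @return Data frame with columns `time_s`, `A340`.
#' @export
generate_activity_trace <- function(initial_rate, duration = 60, dt = 0.1,
                                    A0 = 1, A_inf = 0.1, noise_sd = 0,
                                    seed = 1L) {
  if (initial_rate < 0) stop("'initial_rate' must be >= 0")
  t <- seq(0, duration, by = dt)
  if (initial_rate == 0) {
    y <- rep(A0, length(t))
  } else {
    k <- initial_rate / (A0 - A_inf)
    y <- A_inf + (A0 - A_inf) * exp(-k * t)
  }
  if (noise_sd > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  data.frame(time_s = t, A340 = y)
}
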