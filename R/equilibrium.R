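## Equilibrium-side computations: emission-band integration and
## percent-of-apoenzyme quench tables, spectrum normalization/summation,
## temperature-series correction, and relative activity from initial
## rates of NADPH oxidation.

#' A tryptophan emission spectrum
#'
#' @param wavelength Strictly increasing wavelength vector (nm).
#' @param intensity Intensity (arbitrary units), same length.
#' @param complex_label Complex identifier, e.g. `"apo"`, `"E.Folate"`.
#' @param enzyme Enzyme label.
#' @param temperature Optional temperature (C).
#' @return An object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(wavelength, intensity, complex_label = "apo",
                            enzyme = "", temperature = NA_real_) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity))
    stop("'wavelength' and 'intensity' must have equal length")
  if (any(diff(wavelength) <= 0))
    stop("'wavelength' must be strictly increasing")
  structure(list(wavelength = wavelength, intensity = intensity,
                 complex_label = complex_label, enzyme = enzyme,
                 temperature = temperature),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("Emission spectrum %s%s: %d points, %g-%g nm, peak %.4g at %g nm\n",
              if (nzchar(x$enzyme)) paste0(x$enzyme, " ") else "",
              x$complex_label, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              max(x$intensity), x$wavelength[which.max(x$intensity)]))
  invisible(x)
}

#' @export
as.data.frame.spectrum_record <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, intensity = x$intensity)
}

## Trapezoidal rule on (x, y)
.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

#' Integrate an emission band
#'
#' Trapezoidal integral of the spectrum over `[lo, hi]`, with linear
#' interpolation of the intensity at the band edges when they fall
#' between grid points. The default band, 327-353 nm, matches the
#' bandpass filter of the T-jump fluorescence detection.
#'
#' @param s A [spectrum_record()].
#' @param lo,hi Band limits (nm), `lo < hi`; the band must overlap the
#'   recorded wavelength range.
#' @return The integrated intensity.
#' @export
integrate_band <- function(s, lo = 327, hi = 353) {
  stopifnot(inherits(s, "spectrum_record"))
  if (lo >= hi) stop("'lo' must be below 'hi'")
  wl <- s$wavelength
  if (hi < min(wl) || lo > max(wl))
    stop("band lies outside the recorded wavelength range")
  lo <- max(lo, min(wl)); hi <- min(hi, max(wl))
  inner <- wl > lo & wl < hi
  x <- c(lo, wl[inner], hi)
  y <- stats::approx(wl, s$intensity, xout = x)$y
  .trapz(x, y)
}

#' Integrate the full recorded emission peak
#'
#' @param s A [spectrum_record()] covering the whole emission peak.
#' @return Trapezoidal integral over the full recorded range.
#' @export
integrate_full_peak <- function(s) {
  stopifnot(inherits(s, "spectrum_record"))
  .trapz(s$wavelength, s$intensity)
}

#' Integrated intensity as a percentage of the apoenzyme
#'
#' @param complex_integral Integrated intensity of an enzyme-ligand
#'   complex.
#' @param apo_integral Integrated intensity of the apoenzyme, > 0.
#' @return `100 * complex_integral / apo_integral`.
#' @export
percent_of_apo <- function(complex_integral, apo_integral) {
  if (!is.finite(apo_integral) || apo_integral <= 0)
    stop("'apo_integral' must be positive")
  100 * complex_integral / apo_integral
}

#' Normalize a spectrum to unit peak intensity
#'
#' @param s A [spectrum_record()] with a nonzero maximum.
#' @return The spectrum scaled so its maximum is 1.
#' @export
normalize_spectrum_max <- function(s) {
  stopifnot(inherits(s, "spectrum_record"))
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalize an all-zero (or negative) spectrum")
  s$intensity <- s$intensity / m
  s
}

#' Pointwise sum of emission spectra
#'
#' Spectra are resampled onto the first spectrum's wavelength grid by
#' linear interpolation when grids differ.
#'
#' @param spectra Nonempty list of [spectrum_record()] objects.
#' @param label Complex label of the summed spectrum.
#' @return A [spectrum_record()] holding the sum.
#' @export
sum_spectra <- function(spectra, label = "sum") {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  base <- spectra[[1L]]
  total <- base$intensity
  for (s in spectra[-1L]) {
    stopifnot(inherits(s, "spectrum_record"))
    total <- total + if (identical(s$wavelength, base$wavelength)) s$intensity
                     else stats::approx(s$wavelength, s$intensity,
                                        xout = base$wavelength, rule = 2)$y
  }
  spectrum_record(base$wavelength, total, complex_label = label)
}

#' Temperature series corrected for the intrinsic Trp response
#'
#' Integrated intensities measured across a temperature ladder are
#' normalized to 1 at the lowest temperature, the free-tryptophan
#' reference series (which falls with temperature) is treated the same
#' way, and the reference is subtracted, leaving the change in
#' fluorescence intensity attributable to the enzyme complex. By default
#' normalization precedes subtraction; `order = "subtract_first"`
#' subtracts the raw reference (scaled to the sample at the lowest
#' temperature) before normalizing.
#'
#' @param temperature Temperature grid (C), strictly increasing.
#' @param sample Integrated sample intensities on that grid.
#' @param reference Integrated free-Trp reference intensities on the same
#'   grid.
#' @param order `"normalize_first"` (default) or `"subtract_first"`.
#' @return Data frame with columns `temperature_C` and `delta_intensity`
#'   (change in fluorescence intensity, 0 at the lowest temperature), with
#'   the applied arithmetic recorded in `attr(, "correction")`.
#' @export
temperature_series <- function(temperature, sample, reference,
                               order = c("normalize_first", "subtract_first")) {
  order <- match.arg(order)
  if (length(temperature) != length(sample) ||
      length(sample) != length(reference))
    stop("temperature, sample and reference must share one grid")
  if (any(diff(temperature) <= 0))
    stop("'temperature' must be strictly increasing")
  if (sample[1] == 0 || reference[1] == 0)
    stop("intensity at the lowest temperature must be nonzero")
  if (order == "normalize_first") {
    delta <- sample / sample[1] - reference / reference[1]
  } else {
    corrected <- sample - reference * (sample[1] / reference[1])
    ## corrected[1] is 0 by construction; report change relative to the
    ## lowest-temperature sample intensity
    delta <- corrected / sample[1]
  }
  out <- data.frame(temperature_C = temperature, delta_intensity = delta)
  attr(out, "correction") <- order
  out
}

#' Relative enzymatic activity from initial rates
#'
#' Initial rates are the ordinary-least-squares slopes of the early
#' linear window of each A340-vs-time trace (NADPH oxidation); the result
#' is the sample rate as a percentage of the wild-type rate.
#'
#' @param sample_trace,wt_trace Data frames with columns `time_s` and
#'   `A340`.
#' @param window Fraction of the trace (from the start) used as the
#'   initial linear window (default 0.1).
#' @return Relative activity in percent.
#' @export
relative_activity <- function(sample_trace, wt_trace, window = 0.1) {
  rate <- function(d) {
    stopifnot(all(c("time_s", "A340") %in% names(d)))
    n <- max(3L, ceiling(window * nrow(d)))
    d <- d[seq_len(n), ]
    -unname(stats::coef(stats::lm(A340 ~ time_s, data = d))[2])
  }
  wt <- rate(wt_trace)
  if (abs(wt) < .Machine$double.eps^0.5)
    stop("wild-type initial rate is ~0; relative activity undefined")
  100 * rate(sample_trace) / wt
}
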