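## T-jump transient container and preprocessing: reference subtraction
## and normalization to percent change in fluorescence.

#' A single T-jump fluorescence transient
#'
#' Container for one time course of tryptophan fluorescence following a
#' laser temperature jump, together with the sample metadata the
#' downstream analysis needs. Times may include a pre-jump baseline
#' segment (`time <= 0`); the jump occurs at `time = 0`.
#'
#' @param time Strictly increasing time vector in seconds.
#' @param intensity Fluorescence intensity (arbitrary units, or percent
#'   after normalization), same length as `time`.
#' @param enzyme_total,ligand_total Total concentrations (uM).
#' @param T_initial,T_final Pre- and post-jump temperatures (C).
#' @param replicate Replicate index (integer).
#' @param label Free-text sample label.
#' @param meta Optional list of extra metadata (e.g. ground-truth rates of
#'   a simulated transient, applied corrections).
#' @return An object of class `"transient_record"`.
#' @export
transient_record <- function(time, intensity, enzyme_total = NA_real_,
                             ligand_total = NA_real_, T_initial = NA_real_,
                             T_final = NA_real_, replicate = 1L,
                             label = "", meta = list()) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity))
    stop("'time' and 'intensity' must have equal length")
  if (length(time) < 10L)
    stop("a transient needs at least 10 points")
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing")
  if (!is.na(ligand_total) && ligand_total < 0)
    stop("'ligand_total' must be >= 0")
  structure(list(time = time, intensity = intensity,
                 enzyme_total = enzyme_total, ligand_total = ligand_total,
                 T_initial = T_initial, T_final = T_final,
                 replicate = as.integer(replicate), label = label,
                 meta = meta),
            class = "transient_record")
}

#' @export
print.transient_record <- function(x, ...) {
  cat(sprintf("T-jump transient '%s': %d points, t = [%.3g, %.3g] s\n",
              x$label, length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  enzyme %.4g uM, ligand %.4g uM, jump %.1f -> %.1f C, replicate %d\n",
              x$enzyme_total, x$ligand_total, x$T_initial, x$T_final,
              x$replicate))
  invisible(x)
}

#' @export
as.data.frame.transient_record <- function(x, ...) {
  data.frame(time_s = x$time, intensity = x$intensity)
}

## Indices of the pre-jump window: points at t <= 0 when present,
## otherwise the first `frac` of the trace (at least 2 points).
.prejump_idx <- function(x, frac = 0.01) {
  idx <- which(x$time <= 0)
  if (length(idx) >= 2L) return(idx)
  seq_len(max(2L, ceiling(frac * length(x$time))))
}

#' Pre-jump (initial) intensity of a transient
#'
#' Mean intensity over the pre-jump window: all points at `time <= 0` when
#' the trace includes a pre-jump baseline, otherwise the first `frac`
#' (default 1%) of points, where the relaxation phases have not yet
#' evolved appreciably.
#'
#' @param x A [transient_record()].
#' @param frac Fraction of points used when no `time <= 0` baseline exists.
#' @return Scalar mean initial intensity.
#' @export
prejump_intensity <- function(x, frac = 0.01) {
  stopifnot(inherits(x, "transient_record"))
  mean(x$intensity[.prejump_idx(x, frac)])
}

#' Subtract the intrinsic tryptophan reference from a transient
#'
#' Free tryptophan fluorescence decreases with temperature, so every
#' enzyme transient rides on an intrinsic step that is not kinetic. The
#' reference transient (free Trp measured under the same jump) is
#' resampled onto the sample's time grid, scaled by
#' `s = prejump(sample) / prejump(reference)`, and its change about its
#' own pre-jump level is subtracted:
#' `corrected = sample - s * (reference - prejump(reference))`.
#' Centring the reference preserves the sample's pre-jump intensity so the
#' corrected trace can still be normalized to 100 by its initial value;
#' `center = FALSE` subtracts the scaled reference outright (which nulls
#' the pre-jump level).
#'
#' @param sample,reference [transient_record()] objects. The reference
#'   grid must overlap the sample grid (linear interpolation in between).
#' @param center Subtract the reference's change about its pre-jump level
#'   (default `TRUE`) rather than the full scaled reference.
#' @param frac Pre-jump window fraction, see [prejump_intensity()].
#' @return The corrected [transient_record()]; `meta$reference_scale`
#'   records the applied scale `s`.
#' @export
subtract_reference <- function(sample, reference, center = TRUE, frac = 0.01) {
  stopifnot(inherits(sample, "transient_record"),
            inherits(reference, "transient_record"))
  if (all(reference$intensity == 0)) return(sample)   # nothing to subtract
  if (min(reference$time) > min(sample$time) ||
      max(reference$time) < max(sample$time)) {
    if (max(reference$time) < min(sample$time) ||
        min(reference$time) > max(sample$time))
      stop("reference and sample time grids do not overlap")
  }
  ref_i <- stats::approx(reference$time, reference$intensity,
                         xout = sample$time, rule = 2)$y
  ref_pre <- prejump_intensity(reference, frac)
  if (ref_pre == 0)
    stop("reference pre-jump intensity is zero; cannot scale")
  s <- prejump_intensity(sample, frac) / ref_pre
  corrected <- if (center) sample$intensity - s * (ref_i - ref_pre)
               else        sample$intensity - s * ref_i
  out <- sample
  out$intensity <- corrected
  out$meta$reference_scale <- s
  out$meta$reference_centered <- center
  out
}

#' Normalize a transient to 100 at its initial intensity
#'
#' Divides the whole trace by its pre-jump (initial) intensity and
#' multiplies by 100, so the transient reads as percent change in
#' fluorescence relative to the pre-jump level.
#'
#' @inheritParams prejump_intensity
#' @return The normalized [transient_record()]; `meta$normalization`
#'   records the divisor.
#' @export
normalize_transient <- function(x, frac = 0.01) {
  stopifnot(inherits(x, "transient_record"))
  f0 <- prejump_intensity(x, frac)
  if (!is.finite(f0) || f0 <= 0)
    stop("initial intensity must be positive to normalize")
  out <- x
  out$intensity <- 100 * x$intensity / f0
  out$meta$normalization <- f0
  out
}
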