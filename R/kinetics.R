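## Concentration-dependence analysis of relaxation rates. A relaxation
## phase that tracks the sum of free enzyme and ligand concentrations
## reflects a bimolecular binding step (k = k_on (E_free + L_free) + k_off);
## a phase with no such correlation is a unimolecular conformational
## event. Significance is judged against critical values of the Pearson
## coefficient from the two-tailed t distribution.

#' Pearson product-moment correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the argument checks the
#' classification pipeline relies on.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return The correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Critical value of the Pearson coefficient
#'
#' Threshold above which a correlation is significant at the given
#' two-tailed confidence level: `r_crit = t_c / sqrt(t_c^2 + DF)` with
#' `t_c` the two-tailed Student-t quantile at `DF` degrees of freedom
#' (`DF = n - 2`). At DF = 23 this gives 0.505, 0.337 and 0.265 at the
#' 99%, 90% and 80% levels.
#'
#' @param confidence Confidence level in (0, 1), e.g. 0.99.
#' @param DF Degrees of freedom, `n - 2`, at least 1.
#' @return The critical value of `r`.
#' @examples
#' critical_r(0.99, 23)
#' @export
critical_r <- function(confidence, DF) {
  stopifnot(is.numeric(confidence), is.numeric(DF))
  if (any(confidence <= 0 | confidence >= 1))
    stop("'confidence' must lie strictly between 0 and 1")
  if (any(DF < 1) || any(DF != round(DF)))
    stop("'DF' must be a positive integer")
  tc <- stats::qt(1 - (1 - confidence) / 2, df = DF)
  tc / sqrt(tc^2 + DF)
}

#' Classify a relaxation phase by its concentration dependence
#'
#' Compares a Pearson coefficient with the critical values at the given
#' confidence levels (default 99%, 90%, 80%): `"dependent"` when `r`
#' clears the highest level, `"weakly_dependent"` when it clears the
#' middle level only, `"independent"` otherwise. A negative correlation
#' of a relaxation rate with concentration has no physical meaning and is
#' always classified `"independent"`.
#'
#' @param r Pearson coefficient in `[-1, 1]`.
#' @param n Number of paired observations (`DF = n - 2`).
#' @param levels Decreasing confidence levels; the first defines
#'   "dependent", the second "weakly dependent".
#' @return An object of class `"correlation_test"` with `r`, `n`, `DF`,
#'   the levels and critical values, and the `verdict`.
#' @examples
#' classify_dependence(0.954, 25)
#' classify_dependence(0.366, 25)
#' classify_dependence(-0.4, 25)
#' @export
classify_dependence <- function(r, n, levels = c(0.99, 0.90, 0.80)) {
  stopifnot(length(r) == 1L, is.finite(r), abs(r) <= 1, n >= 3)
  levels <- sort(levels, decreasing = TRUE)
  DF <- as.integer(n) - 2L
  crit <- critical_r(levels, DF)
  verdict <- if (r < 0) "independent"
             else if (r >= crit[1]) "dependent"
             else if (length(crit) >= 2L && r >= crit[2]) "weakly_dependent"
             else "independent"
  structure(list(r = r, n = as.integer(n), DF = DF,
                 confidence_levels = levels, critical_values = crit,
                 verdict = verdict),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Concentration-dependence test: r = %.3f (n = %d, DF = %d) -> %s\n",
              x$r, x$n, x$DF, x$verdict))
  cat("  critical r:",
      paste(sprintf("%.3f @ %.0f%%", x$critical_values,
                    100 * x$confidence_levels), collapse = ", "), "\n")
  invisible(x)
}

#' Linear fit of relaxation rate against the sum of free concentrations
#'
#' Ordinary least squares of `k_fast` on `E_free + L_free`. For a
#' two-state binding relaxation the slope is `k_on` (uM-1 s-1) and the
#' intercept is `k_off` (s-1).
#'
#' @param sum_free Sum of free enzyme and ligand concentrations (uM); at
#'   least 3 distinct values.
#' @param k_fast Fast relaxation rates (s-1), same length.
#' @return List with `k_on`, `k_on_se`, `k_off`, `k_off_se`, `r` and the
#'   underlying `lm` fit.
#' @export
fit_rate_vs_concentration <- function(sum_free, k_fast) {
  stopifnot(length(sum_free) == length(k_fast))
  if (length(unique(sum_free)) < 3L)
    stop("need at least 3 distinct concentration values")
  fit <- stats::lm(k_fast ~ sum_free)
  s <- summary(fit)$coefficients
  list(k_on = unname(s["sum_free", "Estimate"]),
       k_on_se = unname(s["sum_free", "Std. Error"]),
       k_off = unname(s["(Intercept)", "Estimate"]),
       k_off_se = unname(s["(Intercept)", "Std. Error"]),
       r = pearson_r(sum_free, k_fast),
       fit = fit)
}

#' Kinetic dissociation constant from the rate constants
#'
#' For one-step binding, `Kd = k_off / k_on`.
#'
#' @param k_on Association rate constant (uM-1 s-1), > 0.
#' @param k_off Dissociation rate constant (s-1).
#' @return Kd in uM.
#' @examples
#' kd_from_rates(31, 1100)  # 35.5 uM
#' @export
kd_from_rates <- function(k_on, k_off) {
  if (!is.finite(k_on) || k_on <= 0) stop("'k_on' must be positive")
  k_off / k_on
}

#' Pool concentration-independent slow rates
#'
#' The slow relaxation rate does not depend on ligand concentration, so
#' all fits (every replicate at every concentration) are pooled into one
#' mean and sample (n-1) standard deviation.
#'
#' @param slow_rates Vector of fitted slow rates (s-1), length >= 2.
#' @return List with `mean`, `sd`, `n` and `DF` (`n - 2`, the degrees of
#'   freedom of the companion correlation test).
#' @export
pool_slow_rates <- function(slow_rates) {
  slow_rates <- slow_rates[is.finite(slow_rates)]
  if (length(slow_rates) < 2L) stop("need at least 2 slow rates to pool")
  list(mean = mean(slow_rates), sd = stats::sd(slow_rates),
       n = length(slow_rates), DF = length(slow_rates) - 2L)
}

#' Full T-jump relaxation-kinetics analysis for one enzyme
#'
#' End-to-end estimator: preprocesses every transient (free-Trp reference
#' subtraction, normalization to percent change), fits each to a double
#' exponential, computes the sum of free concentrations at the post-jump
#' temperature from the binding parameters, classifies both phases by
#' their concentration dependence, extracts `k_on` and `k_off` from the
#' linear fit of the fast rate, forms the kinetic `Kd = k_off / k_on`,
#' and pools the slow rates. When the fast phase shows no significant
#' concentration dependence, `k_on`, `k_off` and the kinetic Kd are
#' withheld (`NA`) because the slope and intercept have no bimolecular
#' interpretation.
#'
#' @param x A `"tjump_experiment"` from [simulate.kinetic_scenario()], or
#'   a list of [transient_record()] objects.
#' @param binding [binding_parameters()] for the enzyme-ligand pair; when
#'   `x` is a simulated experiment, defaults to its scenario's parameters.
#' @param reference Optional free-Trp reference [transient_record()];
#'   defaults to the experiment's. Set `NULL` to skip the subtraction.
#' @param kd_itc Equilibrium Kd from ITC (uM), used for the
#'   kinetic-vs-calorimetric discrepancy ratio; defaults to `binding`'s
#'   `kd_ref`.
#' @param levels Confidence levels for [classify_dependence()].
#' @param preprocess Run reference subtraction and normalization
#'   (default); set `FALSE` if transients are already percent-change.
#' @param guesses Optional starting rates passed to
#'   [fit_double_exponential()].
#' @param enzyme Label used in printing.
#' @return An object of class `"tjump_kinetics"` with the per-sample fit
#'   table, both correlation tests, `k_on`, `k_off`, `kd_tjump`,
#'   `kd_itc`, the discrepancy ratio and pooled slow statistics.
#'   Supports `print()`, `summary()`, `coef()` and `plot()`.
#' @examples
#' \donttest{
#' exp <- simulate(kinetic_scenario(seed = 7))
#' tjump_kinetics(exp)
#' }
#' @export
tjump_kinetics <- function(x, binding = NULL, reference = NULL,
                           kd_itc = NULL, levels = c(0.99, 0.90, 0.80),
                           preprocess = TRUE, guesses = NULL,
                           enzyme = "enzyme") {
  if (inherits(x, "tjump_experiment")) {
    transients <- x$transients
    if (is.null(reference)) reference <- x$reference
    if (is.null(binding)) binding <- x$scenario$binding
  } else {
    transients <- x
  }
  if (is.null(binding) || !inherits(binding, "binding_parameters"))
    stop("'binding' parameters are required")
  if (is.null(kd_itc)) kd_itc <- binding$kd_ref
  n_conc <- length(unique(vapply(transients, `[[`, numeric(1), "ligand_total")))
  if (n_conc < 3L) stop("need at least 3 ligand concentration levels")

  rows <- list()
  fits <- vector("list", length(transients))
  for (i in seq_along(transients)) {
    tr <- transients[[i]]
    if (preprocess) {
      if (!is.null(reference)) tr <- subtract_reference(tr, reference)
      tr <- normalize_transient(tr)
    }
    ft <- fit_double_exponential(tr, guesses = guesses)
    fits[[i]] <- ft
    Tk <- tr$T_final + 273.15
    sf <- sum_free_at(binding, tr$enzyme_total, tr$ligand_total, Tk)
    cf <- ft$coefficients
    rows[[i]] <- data.frame(
      sample_id = if (nzchar(tr$label)) tr$label else sprintf("sample%03d", i),
      ligand_uM = tr$ligand_total, replicate = tr$replicate,
      sum_free_uM = sf,
      k_fast = cf[["k_fast"]], k_fast_se = ft$se[["k_fast"]],
      k_slow = cf[["k_slow"]], k_slow_se = ft$se[["k_slow"]],
      amp_fast = cf[["amp_fast"]], amp_slow = cf[["amp_slow"]],
      baseline = cf[["baseline"]], rms = ft$rms, converged = ft$converged)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  ok <- tab$converged
  fast_test <- classify_dependence(
    pearson_r(tab$sum_free_uM[ok], tab$k_fast[ok]), sum(ok), levels)
  slow_test <- classify_dependence(
    pearson_r(tab$sum_free_uM[ok], tab$k_slow[ok]), sum(ok), levels)

  line <- fit_rate_vs_concentration(tab$sum_free_uM[ok], tab$k_fast[ok])
  withheld <- fast_test$verdict == "independent"
  k_on <- if (withheld) NA_real_ else line$k_on
  k_off <- if (withheld) NA_real_ else line$k_off
  kd_tjump <- if (withheld) NA_real_ else kd_from_rates(line$k_on, line$k_off)
  slow <- pool_slow_rates(tab$k_slow[ok])

  structure(list(table = tab, fits = fits,
                 k_on = k_on, k_on_se = if (withheld) NA_real_ else line$k_on_se,
                 k_off = k_off, k_off_se = if (withheld) NA_real_ else line$k_off_se,
                 kd_tjump = kd_tjump, kd_itc = kd_itc,
                 kd_ratio = kd_tjump / kd_itc,
                 fast_test = fast_test, slow_test = slow_test,
                 fast_withheld = withheld,
                 slow_mean = slow$mean, slow_sd = slow$sd, slow_n = slow$n,
                 line = line$fit, binding = binding, enzyme = enzyme),
            class = "tjump_kinetics")
}

#' @export
print.tjump_kinetics <- function(x, ...) {
  cat(sprintf("T-jump relaxation kinetics: %s (%d transients, %d converged)\n",
              x$enzyme, nrow(x$table), sum(x$table$converged)))
  cat(sprintf("  fast phase: r = %.3f -> %s\n",
              x$fast_test$r, x$fast_test$verdict))
  cat(sprintf("  slow phase: r = %.3f -> %s\n",
              x$slow_test$r, x$slow_test$verdict))
  if (x$fast_withheld) {
    cat("  k_on/k_off withheld: fast phase shows no significant concentration dependence\n")
  } else {
    cat(sprintf("  k_on  = %.3g +/- %.2g uM-1 s-1\n", x$k_on, x$k_on_se))
    cat(sprintf("  k_off = %.4g +/- %.3g s-1\n", x$k_off, x$k_off_se))
    cat(sprintf("  Kd (kinetic) = %.3g uM vs Kd (ITC) = %.3g uM (ratio %.2g)\n",
                x$kd_tjump, x$kd_itc, x$kd_ratio))
  }
  cat(sprintf("  slow rate: %.4g +/- %.3g s-1 (n = %d)\n",
              x$slow_mean, x$slow_sd, x$slow_n))
  invisible(x)
}

#' @export
coef.tjump_kinetics <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, kd_tjump = object$kd_tjump,
    slow_mean = object$slow_mean)
}

#' @export
summary.tjump_kinetics <- function(object, ...) {
  structure(list(object = object), class = "summary.tjump_kinetics")
}

#' @export
print.summary.tjump_kinetics <- function(x, ...) {
  print(x$object)
  cat("\nPer-sample fits:\n")
  print(x$object$table[, c("sample_id", "ligand_uM", "sum_free_uM",
                           "k_fast", "k_slow", "converged")],
        digits = 4, row.names = FALSE)
  cat("\nCritical r values:",
      paste(sprintf("%.3f @ %.0f%%", x$object$fast_test$critical_values,
                    100 * x$object$fast_test$confidence_levels),
            collapse = ", "),
      sprintf("(DF = %d)\n", x$object$fast_test$DF))
  invisible(x)
}

#' @export
plot.tjump_kinetics <- function(x, which = c("fast", "slow"), ...) {
  which <- match.arg(which)
  tab <- x$table[x$table$converged, ]
  y <- if (which == "fast") tab$k_fast else tab$k_slow
  test <- if (which == "fast") x$fast_test else x$slow_test
  plot(tab$sum_free_uM, y, pch = 16,
       xlab = "free [E] + free [L] (uM)",
       ylab = sprintf("k_%s (s-1)", which),
       main = sprintf("%s phase: r = %.3f (%s)", which, test$r, test$verdict),
       ...)
  if (which == "fast" && !x$fast_withheld)
    graphics::abline(x$line, col = "red3", lwd = 2)
  invisible(x)
}
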