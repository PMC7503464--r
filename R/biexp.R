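## Double-exponential relaxation fit. The model for the post-jump signal
## (percent units after normalization) is
##   F(t) = baseline + a_fast (1 - e^{-k_fast t}) + a_slow (1 - e^{-k_slow t})
## Rising saturating exponentials match a fluorescence increase after the
## jump; amplitudes are signed, so decaying phases are permitted.
## Initialization is by a separable coarse search: for each candidate rate
## pair the amplitudes and baseline are a linear least-squares solve, and
## the best pair seeds a Levenberg-Marquardt refinement.

.biexp_eval <- function(t, p) {
  p[["baseline"]] +
    p[["amp_fast"]] * (1 - exp(-p[["k_fast"]] * t)) +
    p[["amp_slow"]] * (1 - exp(-p[["k_slow"]] * t))
}

## Coarse separable search over log-spaced rate pairs; returns the best
## full parameter vector.
.biexp_grid_init <- function(t, y, n_grid = 24L, min_ratio = 1.5) {
  rates <- exp(seq(log(0.1 / max(t)), log(2 / min(t)), length.out = n_grid))
  basis <- lapply(rates, function(k) 1 - exp(-k * t))
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    if (rates[i] < min_ratio * rates[j]) next   # i indexes the fast rate
    X <- cbind(1, basis[[i]], basis[[j]])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c(baseline = fit$coefficients[[1]],
                amp_fast = fit$coefficients[[2]],
                amp_slow = fit$coefficients[[3]],
                k_fast = rates[i], k_slow = rates[j])
    }
  }
  best[!is.finite(best)] <- 0
  best
}

#' Fit a T-jump transient to a double exponential
#'
#' Least-squares fit of the post-jump signal to a sum of two rising
#' saturating exponentials plus a baseline. Rates are reported sorted so
#' `k_fast >= k_slow`, with standard errors from the covariance of the
#' fit. When no starting rates are supplied, a coarse separable search
#' over log-spaced rate pairs (amplitudes solved linearly at each pair)
#' provides the initial guess, which Levenberg-Marquardt then refines.
#'
#' @param x A [transient_record()] (only points at `time > 0` enter the
#'   fit) or a data frame with columns `time_s`/`time` and `intensity`.
#' @param guesses Optional numeric pair of starting rates
#'   `c(k_fast, k_slow)` (s-1).
#' @param float_baseline Fit the baseline (default). If `FALSE` it is
#'   fixed at the mean of the earliest 1% of post-jump points.
#' @param min_ratio Fast/slow rate ratio below which an identifiability
#'   warning is raised (default 1.5).
#' @return An object of class `"biexp_fit"`: coefficients `baseline`,
#'   `amp_fast`, `amp_slow`, `k_fast`, `k_slow`; standard errors; residual
#'   RMS; a convergence flag; and the fitted data. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()` and
#'   `plot()`.
#' @examples
#' sc <- kinetic_scenario(noise_sd = 0)
#' tr <- normalize_transient(generate_transient(sc, 200))
#' fit_double_exponential(tr)
#' @export
fit_double_exponential <- function(x, guesses = NULL, float_baseline = TRUE,
                                   min_ratio = 1.5) {
  if (inherits(x, "transient_record")) {
    keep <- x$time > 0
    t <- x$time[keep]; y <- x$intensity[keep]
    label <- x$label
  } else {
    d <- as.data.frame(x)
    tc <- if ("time_s" %in% names(d)) "time_s" else "time"
    t <- d[[tc]]; y <- d$intensity
    keep <- t > 0
    t <- t[keep]; y <- y[keep]
    label <- ""
  }
  if (length(t) < 10L) stop("need at least 10 post-jump points to fit")

  if (!is.null(guesses)) {
    stopifnot(is.numeric(guesses), length(guesses) == 2L, all(guesses > 0))
    kf0 <- max(guesses); ks0 <- min(guesses)
    X <- cbind(1, 1 - exp(-kf0 * t), 1 - exp(-ks0 * t))
    cf <- stats::lm.fit(X, y)$coefficients
    cf[!is.finite(cf)] <- 0
    start <- c(baseline = cf[[1]], amp_fast = cf[[2]], amp_slow = cf[[3]],
               k_fast = kf0, k_slow = ks0)
  } else {
    start <- .biexp_grid_init(t, y)
  }

  fixed_baseline <- NULL
  if (!float_baseline) {
    n0 <- max(2L, ceiling(0.01 * length(t)))
    fixed_baseline <- mean(y[seq_len(n0)])
    start <- start[c("amp_fast", "amp_slow", "k_fast", "k_slow")]
  }

  dat <- data.frame(t = t, y = y)
  form <- if (float_baseline)
    y ~ baseline + amp_fast * (1 - exp(-k_fast * t)) +
      amp_slow * (1 - exp(-k_slow * t))
  else
    stats::as.formula(sprintf(
      "y ~ %.17g + amp_fast * (1 - exp(-k_fast * t)) + amp_slow * (1 - exp(-k_slow * t))",
      fixed_baseline))
  lower <- rep(-Inf, length(start))
  names(lower) <- names(start)
  lower[c("k_fast", "k_slow")] <- 1e-12

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = as.list(start),
                      lower = lower,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    cf <- start
    if (!float_baseline) cf <- c(baseline = fixed_baseline, cf)
    se <- rep(NA_real_, 5)
    names(se) <- c("baseline", "amp_fast", "amp_slow", "k_fast", "k_slow")
    converged <- FALSE
    rms <- sqrt(mean((y - .biexp_eval(t, as.list(cf)))^2))
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) {
                     out <- rep(NA_real_, length(cf)); names(out) <- names(cf); out
                   })
    if (!float_baseline) {
      cf <- c(baseline = fixed_baseline, cf)
      se <- c(baseline = 0, se)
    }
    converged <- fit$convInfo$isConv %||% TRUE
    rms <- sqrt(mean(stats::residuals(fit)^2))
  }

  ## enforce rate ordering k_fast >= k_slow
  if (cf[["k_fast"]] < cf[["k_slow"]]) {
    cf[c("k_fast", "k_slow")] <- cf[c("k_slow", "k_fast")]
    cf[c("amp_fast", "amp_slow")] <- cf[c("amp_slow", "amp_fast")]
    se[c("k_fast", "k_slow")] <- se[c("k_slow", "k_fast")]
    se[c("amp_fast", "amp_slow")] <- se[c("amp_slow", "amp_fast")]
  }
  ord <- c("baseline", "amp_fast", "amp_slow", "k_fast", "k_slow")
  cf <- cf[ord]; se <- se[ord]

  identifiable <- TRUE
  if (converged && cf[["k_slow"]] > 0 &&
      cf[["k_fast"]] / cf[["k_slow"]] < min_ratio) {
    identifiable <- FALSE
    warning(sprintf(
      "fast/slow rate ratio %.2f < %.2f: the two phases are poorly identifiable",
      cf[["k_fast"]] / cf[["k_slow"]], min_ratio))
  }
  if (converged && max(t) < 3 / cf[["k_slow"]])
    warning("time window shorter than 3/k_slow; slow rate may be poorly determined")

  structure(list(coefficients = cf, se = se, rms = rms,
                 converged = converged, identifiable = identifiable,
                 data = data.frame(time_s = t, intensity = y),
                 label = label),
            class = "biexp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.biexp_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Double-exponential relaxation fit%s:\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  cat(sprintf("  k_fast = %.4g +/- %.2g s-1, amp %.3g\n",
              cf[["k_fast"]], x$se[["k_fast"]], cf[["amp_fast"]]))
  cat(sprintf("  k_slow = %.4g +/- %.2g s-1, amp %.3g\n",
              cf[["k_slow"]], x$se[["k_slow"]], cf[["amp_slow"]]))
  cat(sprintf("  baseline %.4g, residual RMS %.3g, converged: %s\n",
              cf[["baseline"]], x$rms, x$converged))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) object$coefficients

#' @export
summary.biexp_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std_error = object$se)
  structure(list(coefficients = tab, rms = object$rms,
                 converged = object$converged,
                 n = nrow(object$data), label = object$label),
            class = "summary.biexp_fit")
}

#' @export
print.summary.biexp_fit <- function(x, ...) {
  cat(sprintf("Double-exponential fit on %d points%s\n", x$n,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  print(round(x$coefficients, 6))
  cat(sprintf("Residual RMS %.4g; converged: %s\n", x$rms, x$converged))
  invisible(x)
}

#' @export
predict.biexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s
       else if (is.numeric(newdata)) newdata
       else (newdata$time_s %||% newdata$time)
  .biexp_eval(t, as.list(object$coefficients))
}

#' @export
fitted.biexp_fit <- function(object, ...) predict(object)

#' @export
residuals.biexp_fit <- function(object, ...)
  object$data$intensity - fitted(object)

#' @export
plot.biexp_fit <- function(x, ...) {
  plot(x$data$time_s, x$data$intensity, log = "x", pch = 16, cex = 0.4,
       col = "grey40", xlab = "time (s)",
       ylab = "fluorescence (% of initial)",
       main = if (nzchar(x$label)) x$label else "T-jump transient", ...)
  tt <- exp(seq(log(min(x$data$time_s)), log(max(x$data$time_s)),
                length.out = 400))
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  invisible(x)
}
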