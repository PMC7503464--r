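test_that("band integration matches simple areas and is linear", {
  s <- spectrum_record(300:420, rep(1, 121))
  expect_equal(integrate_band(s, 327, 353), 26)      # rectangle area
  half <- spectrum_record(300:420, rep(0.5, 121))
  expect_equal(integrate_band(half, 327, 353),
               integrate_band(s, 327, 353) / 2)      # homogeneity
  # additivity over adjacent bands
  set.seed(12)
  g <- spectrum_record(300:420, runif(121, 0.5, 2))
  expect_equal(integrate_band(g, 310, 335) + integrate_band(g, 335, 380),
               integrate_band(g, 310, 380), tolerance = 1e-12)
  # edge interpolation: band limits between grid points
  expect_equal(integrate_band(s, 327.3, 352.7), 25.4, tolerance = 1e-12)
  expect_error(integrate_band(s, 353, 327), "below")
  expect_error(integrate_band(s, 500, 600), "outside")
})

test_that("a narrow Gaussian band integrates to amp * sigma * sqrt(2 pi)", {
  wl <- seq(300, 420, by = 1)
  amp <- 10; ctr <- 340; sig <- 3
  s <- spectrum_record(wl, amp * exp(-(wl - ctr)^2 / (2 * sig^2)))
  want <- amp * sig * sqrt(2 * pi)                   # closed form
  expect_equal(integrate_band(s, 327, 353), want, tolerance = 5e-3)
  expect_equal(integrate_full_peak(s), want, tolerance = 5e-3)
})

test_that("percent of apoenzyme is a plain scale-invariant ratio", {
  expect_equal(percent_of_apo(100, 100), 100)
  expect_equal(percent_of_apo(71, 100), 71)
  expect_equal(percent_of_apo(7.1, 10), percent_of_apo(71, 100))
  expect_error(percent_of_apo(50, 0), "positive")
})

test_that("configured quench factors survive the full integrate/percent pipeline", {
  # midW22 preset: E.NADP 102%, E.Folate 52%, E.NADP.Folate 49% of apo
  sc <- midw_spectral_scenario("midW22", noise_sd = 0.005, seed = 42)
  apo <- integrate_full_peak(generate_spectrum(sc, "apo"))
  got <- vapply(c(E.NADP = "E.NADP", E.Folate = "E.Folate",
                  E.NADP.Folate = "E.NADP.Folate"),
                function(lab) percent_of_apo(
                  integrate_full_peak(generate_spectrum(sc, lab)), apo),
                numeric(1))
  expect_equal(unname(got), c(102, 52, 49), tolerance = 0.02)
})

test_that("normalization and summation of spectra behave pointwise", {
  wl <- seq(300, 420, by = 1)
  s <- spectrum_record(wl, 7 * exp(-(wl - 345)^2 / 200))
  expect_equal(max(normalize_spectrum_max(s)$intensity), 1)
  summed <- sum_spectra(list(s, s))
  expect_equal(summed$intensity, 2 * s$intensity)
  expect_equal(normalize_spectrum_max(summed)$intensity,
               normalize_spectrum_max(s)$intensity, tolerance = 1e-12)
  zero <- spectrum_record(wl, rep(0, length(wl)))
  expect_error(normalize_spectrum_max(zero), "all-zero")
})

test_that("the summed single-Trp spectrum is blue-shifted against a red reference", {
  # five preset mutant bands summed; a wild-type-like band placed to the
  # red of the summed peak
  mutants <- c("midW22", "midW30", "midW47", "midW74", "midW133")
  spectra <- lapply(mutants, function(m)
    generate_spectrum(midw_spectral_scenario(m, noise_sd = 0), "apo"))
  summed <- sum_spectra(spectra)
  wt <- generate_spectrum(spectral_scenario(center = 345, noise_sd = 0), "apo")
  peak_at <- function(s) s$wavelength[which.max(s$intensity)]
  expect_lte(peak_at(summed), peak_at(wt))
})

test_that("temperature series corrections zero the lowest temperature", {
  temps <- seq(12, 45, by = 3)
  ref <- 100 - 0.8 * (temps - 12)          # Trp dims with temperature
  sample <- 50 * (1 + 0.01 * (temps - 12)) # complex brightens
  out <- temperature_series(temps, sample, ref)
  expect_equal(out$delta_intensity[1], 0)
  expect_true(all(diff(out$delta_intensity) > 0))
  # sample identical to reference: flat zero change
  flat <- temperature_series(temps, ref, ref)
  expect_equal(flat$delta_intensity, rep(0, length(temps)))
  # flat reference: output is the normalized sample minus 1
  out2 <- temperature_series(temps, sample, rep(3, length(temps)))
  expect_equal(out2$delta_intensity, sample / sample[1] - 1)
  # both orders agree at the grid start and record their arithmetic
  alt <- temperature_series(temps, sample, ref, order = "subtract_first")
  expect_equal(alt$delta_intensity[1], 0)
  expect_equal(attr(alt, "correction"), "subtract_first")
  expect_error(temperature_series(temps, sample, ref[-1]), "share")
})

test_that("noiseless melt fits recover the configured Tm to 0.1 C", {
  for (tm in c(48, 42)) {
    fit <- fit_melt(generate_melt_curve(Tm = tm, noise_sd = 0))
    expect_true(fit$converged)
    expect_equal(coef(fit)[["Tm"]], tm, tolerance = 0.1 / tm)
    expect_gt(coef(fit)[["width"]], 0)
  }
  # standard errors are reported numbers on noisy data
  nf <- fit_melt(generate_melt_curve(Tm = 45, noise_sd = 0.15, seed = 9))
  expect_true(is.finite(nf$se[["Tm"]]))
})

test_that("a flat melt curve is flagged as non-convergent", {
  flat <- data.frame(temperature_C = seq(10, 90, by = 5),
                     ellipticity = rep(-8, 17))
  expect_false(fit_melt(flat)$converged)
})

test_that("melt Tm is recovered within 1 C in at least 95% of noisy repeats", {
  hits <- 0L
  for (i in 1:100) {
    m <- generate_melt_curve(Tm = 48, width = 2.5, baselines = c(-12, -2),
                             noise_sd = 0.2, seed = 1000L + i)
    fit <- fit_melt(m)
    if (fit$converged && abs(coef(fit)[["Tm"]] - 48) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("relative activity is the ratio of initial-rate slopes", {
  wt <- generate_activity_trace(0.010, noise_sd = 0)
  expect_equal(relative_activity(wt, wt), 100)
  # exactly proportional traces: ratio is exact
  prop <- wt; prop$A340 <- 0.9 * wt$A340
  expect_equal(relative_activity(prop, wt), 90, tolerance = 1e-12)
  # generator pair with rate ratio 0.9: small curvature bias only
  mut <- generate_activity_trace(0.009, noise_sd = 0)
  expect_equal(relative_activity(mut, wt), 90, tolerance = 5e-3)
  flat <- generate_activity_trace(0, noise_sd = 0)
  expect_equal(relative_activity(flat, wt), 0, tolerance = 1e-9)
  expect_error(relative_activity(wt, flat), "undefined")
})
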