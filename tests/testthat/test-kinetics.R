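test_that("pearson_r reproduces hand-computed coefficients", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  # frozen value from the covariance formula evaluated by hand
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 5)), 0.8315218,
               tolerance = 1e-6)
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("critical r reproduces the printed significance thresholds", {
  # DF = 23 (5 concentrations x 5 replicates)
  expect_equal(round(critical_r(0.99, 23), 3), 0.505)
  expect_equal(round(critical_r(0.90, 23), 3), 0.337)
  expect_equal(round(critical_r(0.80, 23), 3), 0.265)
  expect_error(critical_r(1.2, 23), "between 0 and 1")
  expect_error(critical_r(0.9, 0), "positive integer")
})

test_that("critical r agrees with the p-value-inversion oracle", {
  for (DF in c(3, 7, 23, 50, 100))
    for (conf in c(0.80, 0.90, 0.99))
      expect_equal(critical_r(conf, DF), oracle_critical_r(conf, DF),
                   tolerance = 1e-6)
})

test_that("critical r is monotone in DF and in confidence", {
  dfs <- 3:100
  for (conf in c(0.80, 0.95, 0.99))
    expect_true(all(diff(critical_r(conf, dfs)) < 0))
  confs <- seq(0.5, 0.995, by = 0.005)
  for (DF in c(5, 23, 60))
    expect_true(all(diff(critical_r(confs, DF)) > 0))
})

test_that("phase classification follows the confidence ladder", {
  expect_equal(classify_dependence(0.954, 25)$verdict, "dependent")
  expect_equal(classify_dependence(0.366, 25)$verdict, "weakly_dependent")
  expect_equal(classify_dependence(0.124, 25)$verdict, "independent")
  # negative correlation with concentration is nonsensical -> independent
  expect_equal(classify_dependence(-0.659, 25)$verdict, "independent")
  ct <- classify_dependence(0.7, 25)
  expect_equal(ct$DF, 23L)
  expect_true(all(diff(ct$critical_values) < 0))
})

test_that("rate-vs-concentration line recovers k_on and k_off", {
  conc <- c(30, 60, 90, 120, 150)
  k <- 31 * conc + 1100          # exact line with the reference constants
  fit <- suppressWarnings(fit_rate_vs_concentration(conc, k))
  expect_equal(fit$k_on, 31, tolerance = 1e-12)
  expect_equal(fit$k_off, 1100, tolerance = 1e-9)
  expect_equal(fit$r, 1)
  expect_error(fit_rate_vs_concentration(rep(10, 5), k), "distinct")
  # noisy line: estimates within 2 standard errors of truth
  set.seed(7)
  conc25 <- rep(conc, each = 5)
  k25 <- 31 * conc25 + 1100 + rnorm(25, sd = 80)
  nf <- fit_rate_vs_concentration(conc25, k25)
  expect_lt(abs(nf$k_on - 31), 2 * nf$k_on_se)
  expect_lt(abs(nf$k_off - 1100), 2 * nf$k_off_se)
})

test_that("Kd from rate constants is k_off / k_on", {
  expect_equal(round(kd_from_rates(31, 1100), 1), 35.5)
  expect_equal(kd_from_rates(31, 0), 0)
  expect_equal(kd_from_rates(50, 500), 10)
  expect_error(kd_from_rates(0, 100), "positive")
})

test_that("slope/intercept then Kd reproduces the generating Kd exactly", {
  kd_gen <- 35
  k_on <- 22
  conc <- c(20, 50, 110, 180)
  k <- k_on * conc + k_on * kd_gen   # k_off = k_on * Kd
  fit <- suppressWarnings(fit_rate_vs_concentration(conc, k))
  expect_equal(kd_from_rates(fit$k_on, fit$k_off), kd_gen, tolerance = 1e-9)
})

test_that("slow-rate pooling reports mean, sample sd, n and DF", {
  p <- pool_slow_rates(rep(400, 25))
  expect_equal(p$mean, 400)
  expect_equal(p$sd, 0)
  expect_equal(p$n, 25L)
  expect_equal(p$DF, 23L)
  p <- pool_slow_rates(c(1, 2, 3))
  expect_equal(p$mean, 2)
  expect_equal(p$sd, 1)
  expect_error(pool_slow_rates(400), "at least 2")
})

test_that("pooled slow rates of the replicated noisy design are unbiased", {
  exp1 <- simulate(kinetic_scenario(seed = 314))
  res <- suppressWarnings(tjump_kinetics(exp1))
  expect_lt(abs(res$slow_mean - 400) / 400, 0.10)
  expect_equal(res$slow_n, 25L)
})

test_that("end-to-end summary classifies fast dependent, slow independent", {
  exp1 <- simulate(kinetic_scenario(seed = 7))
  res <- suppressWarnings(tjump_kinetics(exp1))
  expect_equal(res$fast_test$verdict, "dependent")
  expect_equal(res$slow_test$verdict, "independent")
  expect_false(res$fast_withheld)
  # kinetic Kd self-consistency and discrepancy bookkeeping
  expect_equal(res$kd_tjump, res$k_off / res$k_on)
  expect_equal(res$kd_ratio, res$kd_tjump / res$kd_itc)
  expect_equal(res$fast_test$n - 2L, 23L)
})

test_that("k_on/k_off are withheld when the fast phase is not concentration dependent", {
  # constructed null: both phases concentration independent
  t <- c(seq(-5e-4, -5e-7, length.out = 64),
         exp(seq(log(1e-6), log(1e-2), length.out = 1000)))
  transients <- list()
  idx <- 0L
  set.seed(55)
  for (L in c(25, 100, 200)) for (r in 1:3) {
    idx <- idx + 1L
    post <- t > 0
    f <- rep(1, length(t))
    f[post] <- 1 + 0.12 * (1 - exp(-3000 * t[post])) +
      0.08 * (1 - exp(-400 * t[post]))
    f <- f + rnorm(length(f), sd = 0.01)
    transients[[idx]] <- transient_record(
      t, f, enzyme_total = 100, ligand_total = L, T_initial = 29,
      T_final = 36, replicate = r, label = sprintf("null_%d", idx))
  }
  res <- suppressWarnings(tjump_kinetics(
    transients, binding = binding_parameters(4.7, -10), reference = NULL))
  expect_equal(res$fast_test$verdict, "independent")
  expect_true(res$fast_withheld)
  expect_true(is.na(res$k_on) && is.na(res$k_off) && is.na(res$kd_tjump))
})
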