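test_that("reference subtraction removes the intrinsic Trp step", {
  sc <- noiseless_scenario()
  tr <- generate_transient(sc, 100)
  ref <- generate_reference_transient(sc)
  corrected <- subtract_reference(tr, ref)
  # the pure kinetic signal, built separately from the closed form
  kf <- true_fast_rates(sc, 100)
  pure <- vapply(tr$time, oracle_transient_value, numeric(1),
                 f0 = sc$f0, amp_fast = sc$amp_fast, k_fast = kf,
                 amp_slow = sc$amp_slow, k_slow = sc$k_slow, bg_step = 0)
  rms <- sqrt(mean((corrected$intensity - pure)^2)) / sc$f0
  expect_lt(rms, 1e-3)
  expect_equal(corrected$meta$reference_scale,
               prejump_intensity(tr) / prejump_intensity(ref))
})

test_that("a zero reference leaves the sample unchanged", {
  sc <- noiseless_scenario()
  tr <- generate_transient(sc, 50)
  zero <- tr; zero$intensity <- rep(0, length(tr$time))
  expect_identical(subtract_reference(tr, zero)$intensity, tr$intensity)
})

test_that("a sample that is a pure scaled reference has no kinetic signal", {
  sc <- noiseless_scenario()
  ref <- generate_reference_transient(sc)
  copy <- ref; copy$intensity <- 0.3 * ref$intensity
  corrected <- subtract_reference(copy, ref)
  # centred subtraction leaves a flat trace at the sample's pre-jump level
  expect_equal(diff(range(corrected$intensity)), 0, tolerance = 1e-12)
  # the literal (uncentred) form nulls the trace entirely
  full <- subtract_reference(copy, ref, center = FALSE)
  expect_equal(max(abs(full$intensity)), 0, tolerance = 1e-12)
})

test_that("normalization scales the pre-jump window to 100", {
  sc <- noiseless_scenario()
  tr <- generate_transient(sc, 100)
  # constant trace
  const <- tr; const$intensity <- rep(5, length(tr$time))
  expect_equal(unique(normalize_transient(const)$intensity), 100)
  # scale invariance: normalize(7 x) == normalize(x)
  scaled <- tr; scaled$intensity <- 7 * tr$intensity
  expect_equal(normalize_transient(scaled)$intensity,
               normalize_transient(tr)$intensity, tolerance = 1e-12)
  # generated fixture: initial 100, rising signal ends above 100
  norm <- normalize_transient(subtract_reference(
    tr, generate_reference_transient(sc)))
  expect_equal(prejump_intensity(norm), 100, tolerance = 1e-12)
  expect_gt(norm$intensity[length(norm$intensity)], 100)
  # zero initial intensity is an error
  zero <- tr; zero$intensity <- rep(0, length(tr$time))
  expect_error(normalize_transient(zero), "positive")
})

test_that("record validation enforces the container invariants", {
  expect_error(transient_record(1:5, 1:4), "equal length")
  expect_error(transient_record(c(1:9, 9), rep(1, 10)), "increasing")
  expect_error(transient_record(1:5, 1:5), "at least 10")
  expect_error(transient_record(1:10, 1:10, ligand_total = -1), ">= 0")
})

test_that("noiseless double-exponential fits recover both rates exactly", {
  sc <- noiseless_scenario()
  for (L in c(25, 100, 200)) {
    tr <- normalize_transient(subtract_reference(
      generate_transient(sc, L), generate_reference_transient(sc)))
    ft <- suppressWarnings(fit_double_exponential(tr))
    truth_kf <- true_fast_rates(sc, L)
    expect_true(ft$converged)
    expect_lt(abs(coef(ft)[["k_fast"]] - truth_kf) / truth_kf, 1e-3)
    expect_lt(abs(coef(ft)[["k_slow"]] - 400) / 400, 1e-3)
    expect_gte(coef(ft)[["k_fast"]], coef(ft)[["k_slow"]])
  }
})

test_that("degenerate single-exponential input yields a null slow amplitude", {
  sc <- noiseless_scenario(amp_slow = 0, bg_step = 0)
  tr <- normalize_transient(generate_transient(sc, 200))
  ft <- suppressWarnings(fit_double_exponential(tr))
  kf <- true_fast_rates(sc, 200)
  cf <- coef(ft)
  # the effective model must be the single true exponential: either the
  # slow amplitude vanishes or the two rates collapse onto the true rate
  # (amplitude split), in which case the collapse is flagged
  expect_equal(cf[["k_fast"]], kf, tolerance = 1e-4)
  collapsed <- abs(cf[["k_slow"]] - kf) / kf < 1e-3
  expect_true(abs(cf[["amp_slow"]]) < 1e-6 || (collapsed && !ft$identifiable))
  expect_equal(cf[["amp_fast"]] + cf[["amp_slow"]], 100 * sc$amp_fast,
               tolerance = 1e-6)
  expect_lt(ft$rms, 1e-8)
})

test_that("a flat trace is flagged rather than silently reported", {
  t <- exp(seq(log(1e-6), log(1e-2), length.out = 200))
  tr <- transient_record(t, rep(100, 200))
  ft <- suppressWarnings(fit_double_exponential(tr))
  expect_equal(unname(abs(coef(ft)[c("amp_fast", "amp_slow")])), c(0, 0),
               tolerance = 1e-6)
  expect_false(ft$converged && ft$identifiable)
})

test_that("refitting a fit's own noiseless curve is idempotent", {
  sc <- noiseless_scenario()
  tr <- normalize_transient(subtract_reference(
    generate_transient(sc, 150), generate_reference_transient(sc)))
  f1 <- suppressWarnings(fit_double_exponential(tr))
  clone <- tr; clone$intensity <- predict(f1, tr$time)
  clone$intensity[tr$time <= 0] <- 100
  f2 <- suppressWarnings(fit_double_exponential(clone))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
})

test_that("supplied starting rates and fixed baseline are honoured", {
  sc <- noiseless_scenario()
  tr <- normalize_transient(subtract_reference(
    generate_transient(sc, 200), generate_reference_transient(sc)))
  kf <- true_fast_rates(sc, 200)
  ft <- suppressWarnings(fit_double_exponential(tr, guesses = c(5000, 300)))
  expect_equal(coef(ft)[["k_fast"]], kf, tolerance = 1e-4)
  ffix <- suppressWarnings(fit_double_exponential(tr, float_baseline = FALSE))
  expect_equal(coef(ffix)[["k_fast"]], kf, tolerance = 0.05)
})

test_that("rates are recovered under the full replicated noisy design", {
  # 1% noise, 5 concentrations x 5 replicates: the fitted rates should
  # track truth with small median error and never violate the ordering
  exp1 <- simulate(kinetic_scenario(seed = 2024))
  res <- suppressWarnings(tjump_kinetics(exp1))
  tab <- res$table
  expect_true(all(tab$converged))
  expect_true(all(tab$k_fast >= tab$k_slow))
  kf_err <- abs(tab$k_fast - exp1$truth$k_fast) / exp1$truth$k_fast
  ks_err <- abs(tab$k_slow - exp1$truth$k_slow) / exp1$truth$k_slow
  expect_lte(median(kf_err), 0.05)
  expect_lte(median(ks_err), 0.10)
})
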