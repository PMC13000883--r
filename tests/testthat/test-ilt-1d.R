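# 1D inverse Laplace transform: delta recovery, oracle equivalence,
# Tikhonov monotonicity, alpha selection and peak detection.

test_that("a noiseless monoexponential decay inverts to a delta-like peak", {
  cg <- short_cpmg_grid(1200)
  cv <- decay_curve(cg, cpmg_signal(cg$times_s, 1, 0.8))
  sp <- invert_1d(cv, alpha = 1e-3)
  expect_true(all(sp$amplitude >= 0))
  pk <- detect_peaks_1d(sp)
  expect_equal(nrow(pk[!pk$minor, ]), 1)
  in_window <- sp$grid_s >= 0.8 / 1.25 & sp$grid_s <= 0.8 * 1.25
  expect_gte(sum(sp$amplitude[in_window]) / sum(sp$amplitude), 0.95)
  # mass conservation at small alpha
  expect_equal(sum(sp$amplitude), 1, tolerance = 0.05)
})

test_that("solution matches the exhaustive active-set oracle on small grids", {
  set.seed(55)
  grid10 <- exp(seq(log(0.05), log(5), length.out = 10))
  t <- exp(seq(log(0.02), log(8), length.out = 18))
  g <- acquisition_grid("CPMG", times_s = t)
  for (i in 1:5) {
    truthT <- sample(grid10, 2)
    s <- cpmg_signal(t, 0.7, truthT[1]) + cpmg_signal(t, 0.3, truthT[2]) +
      rnorm(18, 0, 0.002)
    alpha <- 0.01
    sp <- invert_1d(decay_curve(g, s), grid_s = grid10, alpha = alpha)
    smax <- max(abs(s))
    A <- rbind(build_kernel("CPMG", grid10, times_s = t),
               alpha * diag(10))
    oracle <- smax * nnls_exhaustive(A, c(s / smax, numeric(10)))
    expect_equal(sp$amplitude, oracle, tolerance = 1e-8)
  }
})

test_that("bi-exponential T1 signal resolves into two accurate peaks", {
  set.seed(66)
  # longer T1 sampling than the default instrument grid to separate pools
  g <- acquisition_grid("SR",
                        times_s = exp(seq(log(0.02), log(12),
                                          length.out = 40)))
  s <- sr_signal(g$times_s, 0.7, 1.75) + sr_signal(g$times_s, 0.3, 0.65)
  s <- s + rnorm(40, 0, max(s) / 500)
  sp <- invert_1d(decay_curve(g, s), alpha = 1e-3)
  pk <- detect_peaks_1d(sp)
  pk <- pk[!pk$minor, ]
  expect_gte(nrow(pk), 2)
  expect_lt(abs(pk$center_s[1] / 1.75 - 1), 0.15)
  expect_lt(abs(pk$center_s[2] / 0.65 - 1), 0.15)
  expect_lt(abs(pk$mass_fraction[1] - 0.7), 0.1)
  expect_lt(abs(pk$mass_fraction[2] - 0.3), 0.1)
  # oracle: same augmented problem on a 4x finer grid; centroids must agree
  # within one coarse grid step
  fine <- default_relax_grid(256)
  spf <- invert_1d(decay_curve(g, s), grid_s = fine, alpha = 1e-3)
  pkf <- detect_peaks_1d(spf)
  pkf <- pkf[!pkf$minor, ]
  step <- (10 / 0.01)^(1 / 63)
  expect_lt(abs(log(pk$center_s[1] / pkf$center_s[1])), log(step))
  expect_lt(abs(log(pk$center_s[2] / pkf$center_s[2])), log(step))
})

test_that("zero signal gives a zero spectrum and no peaks", {
  cg <- short_cpmg_grid(50)
  sp <- invert_1d(decay_curve(cg, numeric(50)), alpha = 0.01)
  expect_true(all(sp$amplitude == 0))
  expect_equal(nrow(detect_peaks_1d(sp)), 0)
})

test_that("solution norm shrinks and residual grows along the alpha ladder", {
  set.seed(77)
  cg <- short_cpmg_grid(300)
  s <- cpmg_signal(cg$times_s, 1, 0.6) + rnorm(300, 0, 0.01)
  cv <- decay_curve(cg, s)
  ladder <- exp(seq(log(1e-4), log(1), length.out = 10))
  sols <- lapply(ladder, function(a) invert_1d(cv, alpha = a))
  xn <- vapply(sols, function(sp) sqrt(sum(sp$amplitude^2)), 1)
  rn <- vapply(sols, function(sp) sp$residual_norm, 1)
  expect_true(all(diff(xn) <= 1e-9))
  expect_true(all(diff(rn) >= -1e-9))
})

test_that("alpha selection: fixed passes through, L-curve adapts to noise", {
  cg <- short_cpmg_grid(300)
  truth <- cpmg_signal(cg$times_s, 1, 0.6)
  cv <- decay_curve(cg, truth)
  expect_identical(select_alpha(cv, method = "fixed", alpha = 0.01), 0.01)
  expect_error(select_alpha(cv, method = "lcurve", ladder = c(1, 2, 3)),
               "at least 4")
  # noiseless: corner collapses toward small alpha, residual near minimum
  a0 <- select_alpha(cv, method = "lcurve")
  expect_lte(a0, 1e-3)
  ladder <- exp(seq(log(1e-5), log(10), length.out = 25))
  res <- vapply(ladder, function(a) invert_1d(cv, alpha = a)$residual_norm, 1)
  expect_lte(invert_1d(cv, alpha = a0)$residual_norm, 2 * min(res))
  # noisier data selects at least as much regularization (paired truth,
  # instrument-length echo train where the residual floor is resolved)
  set.seed(88)
  g <- default_cpmg_grid()
  truth_full <- cpmg_signal(g$times_s, 1, 0.9)
  noise_full <- rnorm(length(truth_full))
  a_lo <- select_alpha(decay_curve(g, truth_full + noise_full / 5000),
                       method = "lcurve")
  a_hi <- select_alpha(decay_curve(g, truth_full + noise_full / 50),
                       method = "lcurve")
  expect_gte(a_hi, a_lo)
})

test_that("peak detection handles deltas, ties and thresholds", {
  grid <- default_relax_grid(32)
  a <- numeric(32); a[10] <- 2
  pk <- detect_peaks_1d(make_spectrum(grid, a))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mass_fraction, 1.0)
  expect_equal(pk$center_s, grid[10])
  expect_true(pk$low_s < pk$center_s && pk$center_s < pk$high_s)
  # two equal deltas: tie broken by smaller center first
  b <- numeric(32); b[8] <- 1; b[20] <- 1
  pk2 <- detect_peaks_1d(make_spectrum(grid, b))
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$center_s, grid[c(8, 20)])
  expect_error(detect_peaks_1d(make_spectrum(grid, b), 1.5), "0, 1")
  # mass fractions sum to <= 1
  expect_lte(sum(pk2$mass_fraction), 1 + 1e-12)
})

test_that("pooled control spectra land in the reference peak windows", {
  st <- generate_study(study_design(seed = 23))
  sp1 <- invert_1d(pool_control(st, "sr"), alpha = 1e-3)
  pk1 <- detect_peaks_1d(sp1)
  pk1 <- pk1[!pk1$minor, ]
  expect_gte(nrow(pk1), 2)
  expect_true(pk1$center_s[1] >= 1.5 && pk1$center_s[1] <= 2.0)
  expect_true(pk1$center_s[2] >= 0.4 && pk1$center_s[2] <= 0.9)
  sp2 <- invert_1d(pool_control(st, "cpmg"), alpha = 1e-3)
  pk2 <- detect_peaks_1d(sp2)
  expect_true(pk2$center_s[1] >= 0.4 && pk2$center_s[1] <= 1.2)
})
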