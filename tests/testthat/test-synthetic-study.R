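# Synthetic glycation study: kinetics anchors, pool mapping, assay trends,
# determinism and forward-model consistency.

test_that("glycation kinetics hit the printed free-amino endpoints", {
  expect_equal(glycation_trajectory(85, 0)$free_amino_fraction, 1.0)
  expect_equal(glycation_trajectory(85, 0)$g, 0)
  expect_equal(glycation_trajectory(85, 6)$free_amino_fraction, 0.60,
               tolerance = 1e-6)
  expect_equal(glycation_trajectory(70, 48)$free_amino_fraction, 0.70,
               tolerance = 1e-6)
  expect_equal(glycation_trajectory(55, 144)$free_amino_fraction, 0.85,
               tolerance = 1e-6)
  # strictly increasing extent
  tt <- seq(0, 6, by = 0.25)
  g <- vapply(tt, function(t) glycation_trajectory(85, t)$g, 1)
  expect_true(all(diff(g) > 0))
  expect_error(glycation_trajectory(60, 1), "unknown temperature")
})

test_that("alpha pool moves deterministically with glycation extent", {
  set.seed(1)
  c0 <- relaxation_params_from_glycation(list(g = 0))
  expect_equal(c0$alpha$T1_s, 1.75)
  expect_equal(c0$alpha$T2_s, 0.90)
  expect_true(c0$alpha$T1_s >= 1.5 && c0$alpha$T1_s <= 2.0)
  expect_true(c0$alpha$T2_s >= 0.4 && c0$alpha$T2_s <= 1.2)
  c1 <- relaxation_params_from_glycation(list(g = 1))
  expect_equal(c0$alpha$T2_s / c0$alpha$T1_s, 0.9 / 1.75, tolerance = 1e-12)
  expect_equal(c1$alpha$T2_s / c1$alpha$T1_s, 0.45 / 1.30, tolerance = 1e-12)
  expect_error(relaxation_params_from_glycation(list(g = 1.2)), "0, 1")
  # beta pool drawn inside its configured ranges
  set.seed(2)
  for (i in 1:25) {
    b <- relaxation_params_from_glycation(list(g = 0.5))$beta
    expect_true(b$T1_s >= 0.4 && b$T1_s <= 0.9)
    expect_true(b$T2_s >= 0.05 && b$T2_s <= 0.3)
    expect_true(b$amplitude >= 0.05 && b$amplitude <= 0.25)
  }
})

test_that("assay readouts reproduce the reference trends", {
  s0 <- assay_readouts_from_glycation(list(g = 0, free_amino_fraction = 1))
  expect_equal(s0$opa_pct, 100)
  expect_equal(s0$a420, 0.02)  # instrument blank only
  # arm endpoints (noiseless): 85 / 70 / 60 %
  ends <- c(`55` = 144, `70` = 48, `85` = 6)
  opa <- vapply(names(ends), function(a)
    assay_readouts_from_glycation(
      glycation_trajectory(as.numeric(a), ends[[a]]))$opa_pct, 1)
  expect_equal(unname(opa), c(85, 70, 60), tolerance = 1e-6)
  # melanoidin rises late and sharply, Amadori saturates early
  g <- seq(0, 0.95, length.out = 20)
  panels <- lapply(g, function(gg)
    assay_readouts_from_glycation(list(g = gg, free_amino_fraction = 1)))
  a420 <- vapply(panels, `[[`, 1, "a420")
  a294 <- vapply(panels, `[[`, 1, "a294")
  expect_true(all(diff(a420) > 0) && all(diff(a294) > 0))
  expect_true(all(diff(a420, differences = 2) > 0))  # convex (late rise)
  expect_true(all(diff(a294, differences = 2) < 0))  # concave (early plateau)
})

test_that("generated study has the printed layout and is seed-reproducible", {
  st <- generate_study(study_design(seed = 5))
  expect_s3_class(st, "glyco_study")
  expect_length(st$records, (7 + 7 + 6) * 3)
  st2 <- generate_study(study_design(seed = 5))
  expect_identical(study_truth(st), study_truth(st2))
  expect_identical(st$records[[17]]$cpmg$signal, st2$records[[17]]$cpmg$signal)
  st3 <- generate_study(study_design(seed = 6))
  expect_false(identical(st$records[[17]]$cpmg$signal,
                         st3$records[[17]]$cpmg$signal))
  # different seeds share the deterministic alpha-pool trajectory
  expect_identical(study_truth(st)$alpha_T1_s, study_truth(st3)$alpha_T1_s)
})

test_that("noise-free curves equal the kernel forward model exactly", {
  st <- generate_study(tiny_design(snr = Inf))
  r <- st$records[[2]]
  amps <- c(r$components$alpha$amplitude, r$components$beta$amplitude)
  K2 <- build_kernel("CPMG", c(r$components$alpha$T2_s,
                               r$components$beta$T2_s)[order(c(
                                 r$components$alpha$T2_s,
                                 r$components$beta$T2_s))],
                     times_s = r$cpmg$grid$times_s)
  ord <- order(c(r$components$alpha$T2_s, r$components$beta$T2_s))
  expect_equal(as.numeric(K2 %*% amps[ord]), r$cpmg$signal,
               tolerance = 1e-12)
  K1 <- build_kernel("SR", sort(c(r$components$alpha$T1_s,
                                  r$components$beta$T1_s)),
                     times_s = r$sr$grid$times_s)
  ord1 <- order(c(r$components$alpha$T1_s, r$components$beta$T1_s))
  expect_equal(as.numeric(K1 %*% amps[ord1]), r$sr$signal,
               tolerance = 1e-12)
})

test_that("noiseless readouts are strictly monotone in time within arms", {
  st <- generate_study(study_design(snr = Inf, assay_noise_sd = 0,
                                    seed = 9))
  tr <- study_truth(st)
  ass <- study_assays(st)
  for (a in c(55, 70, 85)) {
    sub <- tr[tr$temperature_C == a & tr$replicate == 1, ]
    sub <- sub[order(sub$time_h), ]
    expect_true(all(diff(sub$alpha_T1_s) < 0))
    expect_true(all(diff(sub$alpha_T2_s) < 0))
    expect_true(all(diff(sub$alpha_t2_t1) < 0))
    asub <- ass[ass$temperature_C == a & ass$replicate == 1, ]
    asub <- asub[order(asub$time_h), ]
    expect_true(all(diff(asub$opa_pct) < 0))
  }
})

test_that("design validation rejects malformed arms", {
  expect_error(study_design(arms = list(list(temperature_C = 55,
                                             timepoints_h = c(1, 2),
                                             replicates = 3))),
               "include 0")
  expect_error(study_design(arms = list(list(temperature_C = 55,
                                             timepoints_h = c(0, 2),
                                             replicates = 0))),
               "replicates")
  expect_error(study_design(snr = -5), "snr")
})
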