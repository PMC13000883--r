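# 2D inversion: compression consistency, delta and two-pool recovery,
# pool segmentation and ratio extraction.

# one noiseless single-component surface on a short grid
single_surface <- function(T1 = 1.2, T2 = 0.6, A = 1, grid = short_ircpmg_grid()) {
  cmp <- relaxation_component(A, T1, T2)
  sig <- outer(seq_along(grid$tau2_s), seq_along(grid$tau1_s),
               function(i, j) ircpmg_signal(grid$tau1_s[j], grid$tau2_s[i],
                                            list(cmp)))
  relaxation_surface(grid, sig)
}

test_that("fnnls agrees with pracma::lsqnonneg on random problems", {
  set.seed(99)
  for (i in 1:8) {
    m <- sample(15:30, 1); n <- sample(5:12, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    x1 <- glycorelax:::fnnls(crossprod(A), as.numeric(crossprod(A, b)))
    x2 <- pracma::lsqnonneg(A, b)$x
    expect_equal(x1, x2, tolerance = 1e-8)
  }
})

test_that("full-rank compression is lossless: compressed equals full solver", {
  mg <- default_map_grids(24)
  surf <- single_surface()
  full_r1 <- length(surf$grid$tau1_s)
  full_r2 <- length(surf$grid$tau2_s)
  mc <- invert_2d(surf, mg$t1_grid_s, mg$t2_grid_s, alpha = 0.02,
                  rank_1 = full_r1, rank_2 = full_r2)
  mf <- invert_2d(surf, mg$t1_grid_s, mg$t2_grid_s, alpha = 0.02,
                  method = "full")
  rel <- max(abs(mc$amplitude - mf$amplitude)) / max(mf$amplitude)
  expect_lt(rel, 1e-6)
  expect_equal(mc$residual_norm, mf$residual_norm, tolerance = 1e-6)
})

test_that("rank bounds are enforced and the discarded-singular-value bound holds", {
  mg <- default_map_grids()
  # component placed exactly on map grid nodes so the amplitude matrix is a
  # unit delta and the projection bound is exact
  surf <- single_surface(T1 = mg$t1_grid_s[30], T2 = mg$t2_grid_s[20])
  expect_error(compress_surface(surf, mg$t1_grid_s, mg$t2_grid_s,
                                rank_1 = 11), "rank_1")
  cp <- compress_surface(surf, mg$t1_grid_s, mg$t2_grid_s, 8, 16)
  # the kernel truncation error equals the first discarded singular value
  expect_equal(svd(cp$K1)$d[9], cp$discarded[1])
  expect_equal(svd(cp$K2)$d[17], cp$discarded[2])
  # explicit projection bound for S = K2 X K1' with a unit delta X
  # (||X||_F = 1): err <= d2' * ||K1||_2 + ||K2||_2 * d1'
  Sr <- cp$U2 %*% crossprod(cp$U2, surf$signal %*% cp$U1) %*% t(cp$U1)
  err <- norm(Sr - surf$signal, "F")
  bound <- cp$discarded[2] * svd(cp$K1)$d[1] +
    svd(cp$K2)$d[1] * cp$discarded[1]
  expect_lt(err, bound)
})

test_that("a noiseless single component recovers as one pool at the right spot", {
  surf <- single_surface(T1 = 1.2, T2 = 0.6)
  m <- invert_2d(surf, alpha = 0.02)
  expect_true(all(m$amplitude >= 0))
  pools <- detect_pools(m)
  pools <- pools[!pools$minor, ]
  expect_equal(nrow(pools), 1)
  expect_equal(pools$label, "alpha")
  step <- (5 / 0.02)^(1 / 47)
  expect_lt(abs(log(pools$center_t1_s / 1.2)), log(step))
  expect_lt(abs(log(pools$center_t2_s / 0.6)), log(step))
  expect_lt(abs(pools$ratio_t2_t1 / 0.5 - 1), 0.10)
})

test_that("two components at snr 500 recover with accurate alpha ratios", {
  set.seed(17)
  grid <- short_ircpmg_grid(120)
  comps <- list(relaxation_component(1.0, 1.75, 0.90),
                relaxation_component(0.15, 0.6, 0.15))
  sig <- outer(seq_along(grid$tau2_s), seq_along(grid$tau1_s),
               function(i, j) ircpmg_signal(grid$tau1_s[j], grid$tau2_s[i],
                                            comps))
  sig <- sig + rnorm(length(sig), 0, max(abs(sig)) / 500)
  surf <- relaxation_surface(grid, matrix(sig, nrow(sig)))
  m <- invert_2d(surf)
  pools <- detect_pools(m)
  main <- pools[!pools$minor, ]
  expect_equal(nrow(main), 2)
  expect_lt(abs(main$ratio_t2_t1[1] / (0.9 / 1.75) - 1), 0.10)
  # oracle: uncompressed solver on a coarse 24x24 grid; alpha-pool
  # centroids agree within one coarse grid step
  mg <- default_map_grids(24)
  mo <- invert_2d(surf, mg$t1_grid_s, mg$t2_grid_s, method = "full",
                  alpha = 0.03)
  po <- detect_pools(mo)
  po <- po[!po$minor, ]
  step <- (5 / 0.02)^(1 / 23)
  expect_lt(abs(log(main$center_t1_s[1] / po$center_t1_s[1])), log(step))
  expect_lt(abs(log(main$center_t2_s[1] / po$center_t2_s[1])), log(step))
  # physical half-plane: nearly all mass at T1 >= T2
  mass <- m$amplitude
  onb <- outer(m$t2_grid_s, m$t1_grid_s, FUN = function(t2, t1) t1 >= t2)
  expect_gte(sum(mass[onb]) / sum(mass), 0.95)
})

test_that("zero surfaces give zero maps and empty pool lists", {
  grid <- short_ircpmg_grid(30)
  surf <- relaxation_surface(grid, matrix(0, 30, 10))
  m <- invert_2d(surf)
  expect_true(all(m$amplitude == 0))
  expect_equal(nrow(detect_pools(m)), 0)
})

test_that("pool labeling follows intensity with the documented tie-break", {
  g <- exp(seq(log(0.02), log(5), length.out = 16))
  A <- matrix(0, 16, 16)
  A[4, 8] <- 1    # (T2 small, T1 mid)
  A[10, 14] <- 1  # equal intensity, larger T1
  pools <- suppressWarnings(detect_pools(make_map(g, g, A), gap_fill = 0))
  expect_equal(pools$label[1], "alpha")
  expect_equal(pools$center_t1_s[1], g[14])  # tie -> larger center T1
  expect_equal(pools$label[2], "beta")
  # single delta
  B <- matrix(0, 16, 16); B[6, 10] <- 2
  p1 <- detect_pools(make_map(g, g, B))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$label, "alpha")
  expect_equal(p1$intensity, 2)
  expect_error(detect_pools(make_map(g, g, B), threshold_fraction = 0),
               "0, 1")
})

test_that("unphysical pools warn but are still reported", {
  g <- exp(seq(log(0.02), log(5), length.out = 16))
  A <- matrix(0, 16, 16)
  A[12, 4] <- 1  # T2 > T1
  expect_warning(detect_pools(make_map(g, g, A)), "unphysical")
})

test_that("map-ratio series tracks latent glycation and keeps the reciprocal identity", {
  st <- generate_study(tiny_design(snr = 500, seed = 3, replicates = 2))
  ratios <- pool_ratio_series(st)
  expect_equal(nrow(ratios), length(st$records))
  expect_equal(ratios$t1_t2_map * ratios$t2_t1_map, rep(1, nrow(ratios)),
               tolerance = 1e-12)
  tr <- study_truth(st)
  m <- merge(ratios, tr[, c("sample_id", "g")])
  expect_lte(cor(m$t2_t1_map, m$g, method = "spearman"), -0.9)
  # recovered ratios within 10 % of generator truth
  expect_true(all(abs(m$t2_t1_map / tr$alpha_t2_t1[match(m$sample_id,
    tr$sample_id)] - 1) < 0.10))
})
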