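# Quality metrics: FSC + 1/2-bit threshold, DVF RMS error and PCA,
# histogram bimodality.

test_that("FSC of a volume with itself is 1 and has sane structure", {
  set.seed(4)
  v <- gaussian_smooth3(array(rnorm(64 * 64 * 32), c(64, 64, 32)), 2)
  f <- fsc(v, v)
  expect_true(all(abs(f$correlation - 1) < 1e-8))
  expect_true(all(f$freq <= 0.5 + f$freq[1]))  # last shell midpoint
  expect_true(all(f$threshold > 0 & f$threshold < 1))
  expect_true(is.na(attr(f, "resolution_freq")))

  expect_error(fsc(array(0, c(8, 8, 8)), v[1:8, 1:8, 1:8]), "all-zero")
  expect_error(fsc(v, v[1:8, 1:8, 1:8]), "equal shapes")
})

test_that("FSC separates correlated from uncorrelated content", {
  set.seed(5)
  a <- array(rnorm(64^2 * 64), c(64, 64, 64))
  b <- array(rnorm(64^2 * 64), c(64, 64, 64))
  f_indep <- fsc(a, b)
  expect_lt(abs(mean(f_indep$correlation)), 0.05)

  # signal + strong high-frequency noise: resolution below Nyquist,
  # correlation trending downward
  sig <- gaussian_smooth3(a, 2.5)
  noisy <- sig + 0.5 * sd(sig) * b
  f <- fsc(sig, noisy)
  rf <- attr(f, "resolution_freq")
  expect_false(is.na(rf))
  expect_lt(rf, 0.5)
  n <- nrow(f)
  expect_gt(mean(f$correlation[1:5]), mean(f$correlation[(n - 5):n]))
})

test_that("FSC is symmetric and invariant to joint intensity scaling", {
  set.seed(6)
  a <- gaussian_smooth3(array(rnorm(32^3), c(32, 32, 32)), 2)
  b <- a + 0.3 * array(rnorm(32^3), c(32, 32, 32))
  f1 <- fsc(a, b); f2 <- fsc(b, a)
  expect_equal(f1$correlation, f2$correlation, tolerance = 1e-10)
  f3 <- fsc(2.5 * a, 2.5 * b)
  expect_equal(f1$correlation, f3$correlation, tolerance = 1e-10)
})

test_that("DVF RMS error matches a brute-force loop", {
  gs <- c(8L, 8L, 8L)
  f1 <- fixture_smooth_field(gs, sigma = 2, max_disp = 2, seed = 7)
  f2 <- fixture_smooth_field(gs, sigma = 2, max_disp = 1.5, seed = 8)
  d1 <- fixture_dvf2(f1); d2 <- fixture_dvf2(f2)

  expect_equal(dvf_rms_error(d1, d1), 0)

  cst <- array(0, dim(f1)); cst[, , , 1] <- 1
  expect_equal(dvf_rms_error(fixture_dvf2(f1 + cst), d1, t_samples = 1), 1,
               tolerance = 1e-10)

  # naive double loop over voxels and node times
  acc <- 0; n <- 0
  for (t in c(0, 1)) {
    a1 <- if (t == 0) array(0, dim(f1)) else f1
    a2 <- if (t == 0) array(0, dim(f2)) else f2
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      acc <- acc + sum((a1[i, j, k, ] - a2[i, j, k, ])^2)
      n <- n + 1
    }
  }
  expect_equal(dvf_rms_error(d1, d2), sqrt(acc / n), tolerance = 1e-10)

  # triangle inequality against a third field
  f3 <- fixture_smooth_field(gs, sigma = 2, max_disp = 1, seed = 9)
  d3 <- fixture_dvf2(f3)
  expect_lte(dvf_rms_error(d1, d2),
             dvf_rms_error(d1, d3) + dvf_rms_error(d3, d2) + 1e-12)

  expect_error(dvf_rms_error(d1, d2, mask = array(FALSE, gs)), "empty")
})

test_that("DVF PCA: rank-1 fields, normalization, variance splitting", {
  gs <- c(6L, 6L, 4L)
  F1 <- fixture_smooth_field(gs, sigma = 2, max_disp = 1, seed = 10)
  amp <- c(0, 0.3, 0.7, 1)
  dvf <- dvf4d(c(0, 1 / 3, 2 / 3, 1), lapply(amp, function(a) a * F1), 1L, gs)
  p <- dvf_pca(dvf)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-10)
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-10)
  w <- p$weights[, 1]
  expect_equal(w / w[4], amp, tolerance = 1e-8)

  # two orthogonal modes with amplitude ratio 2:1 -> variance split 0.8/0.2
  F2 <- array(0, c(gs, 3))
  F2[, , , 2] <- 1  # orthogonal to F1 with overwhelming probability
  F2 <- F2 - F1 * sum(F2 * F1) / sum(F1 * F1)
  F1u <- F1 / sqrt(sum(F1^2)); F2u <- F2 / sqrt(sum(F2^2))
  nodes <- list(array(0, c(gs, 3)), 2 * F1u, 1 * F2u)
  d <- dvf4d(c(0, 0.5, 1), nodes, 1L, gs)
  p2 <- dvf_pca(d)
  expect_equal(p2$explained_fraction[1:2], c(0.8, 0.2), tolerance = 1e-8)
})

test_that("histogram report: normalization and blur-sensitive bimodality", {
  cfg <- sim_config(shape = c(40, 40, 20), max_disp = 0, seed = 12)
  ph <- make_phantom(cfg)
  supp <- attr(ph, "support")
  blurred <- gaussian_smooth3(ph$data, 1.5)
  hr <- histogram_report(list(ph, blurred), mask = supp, n_bins = 60)
  expect_equal(colSums(hr$density), c(1, 1), tolerance = 1e-10)
  # binary phantom: essentially two occupied bins, score near zero
  expect_lt(hr$bimodality[1], 1e-6)
  expect_gt(sum(hr$density[, 1] > 0), 0)
  # blur fills the valley between the modes
  expect_gt(hr$bimodality[2], hr$bimodality[1])
})
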