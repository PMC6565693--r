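# DVF estimation: 3-D optical flow and temporal deconvolution.

test_that("flow update vanishes for identical or featureless volumes", {
  vol <- fixture_blob(c(24, 24, 12))
  cfg <- flow_config(kernel_sigma = 4)
  out <- optical_flow_update(vol, vol, cfg = cfg)
  expect_true(all(out == 0))

  # uniform volume: zero gradient everywhere, alpha guards the division
  u <- array(1, c(16, 16, 8))
  out2 <- optical_flow_update(u, u + 0.1, cfg = cfg)
  expect_true(all(out2 == 0))
})

test_that("flow recovers a known sub-voxel translation", {
  vs <- c(32L, 32L, 16L)
  vol <- fixture_blob(vs, sigma = 5)
  shift <- array(0, c(vs, 3)); shift[, , , 1] <- 0.5
  # g_sub(x) = g_full(x - 0.5 e_x): content displaced by +0.5 voxel in x
  g_sub <- warp_volume(vol, fixture_dvf2(-shift), 1)
  cfg <- flow_config(kernel_sigma = 6)
  upd <- optical_flow_update(vol, g_sub, cfg = cfg)
  support <- vol > 0.1 * max(vol)
  expect_gte(mean(upd[, , , 1][support]), 0.3)
  expect_lte(mean(upd[, , , 1][support]), 0.7)
  expect_lt(mean(abs(upd[, , , 2][support])), 0.1)
  expect_lt(mean(abs(upd[, , , 3][support])), 0.1)
})

test_that("repeated update + warp contracts the residual", {
  vs <- c(32L, 32L, 16L)
  vol <- fixture_blob(vs, sigma = 5)
  fld <- fixture_smooth_field(vs, sigma = 8, max_disp = 1.2, seed = 6)
  g_sub <- warp_volume(vol, fixture_dvf2(fld), 1)  # g_sub(x) = vol(x + fld)
  # classic one-step update: the contraction comes from the outer
  # update + warp iteration, not from inner warping
  cfg <- flow_config(kernel_sigma = 6, lambda = 1, n_inner = 1)
  dvf_i <- array(0, c(vs, 3))
  resid <- numeric(4)
  for (k in 1:4) {
    resid[k] <- sqrt(mean((vol - warp_volume(g_sub,
                       fixture_dvf2(-dvf_i), 1))^2))
    upd <- optical_flow_update(g_sub, vol, dvf_i, cfg)
    dvf_i <- upd
  }
  expect_true(all(diff(resid) < 0))
})

test_that("temporal deconvolution solves the midpoint node system", {
  m <- c(4L, 4L, 2L)
  mk <- function(val) { a <- array(0, c(m, 3)); a[, , , 1] <- val; a }

  z <- temporal_deconvolve(list(mk(0), mk(0)), reg_weight = 0)
  expect_true(all(vapply(z$nodes, function(f) all(f == 0), TRUE)))

  # hand-solved 2x2 midpoint system: averages (a, 3a) -> nodes (0, 2a, 4a)
  a <- 0.7
  d <- temporal_deconvolve(list(mk(a), mk(3 * a)), reg_weight = 1e-12)
  expect_equal(d$node_times, c(0, 0.5, 1))
  expect_equal(d$nodes[[2]][1, 1, 1, 1], 2 * a, tolerance = 1e-8)
  expect_equal(d$nodes[[3]][1, 1, 1, 1], 4 * a, tolerance = 1e-8)

  # single block: average a -> end node 2a
  d1 <- temporal_deconvolve(list(mk(a)), reg_weight = 1e-12)
  expect_equal(d1$nodes[[2]][2, 2, 1, 1], 2 * a, tolerance = 1e-8)

  expect_error(temporal_deconvolve(list()), "at least one")
})

test_that("deconvolution reproduces any midpoint-consistent node sequence", {
  m <- c(3L, 3L, 2L)
  set.seed(9)
  nodes_true <- c(0, cumsum(runif(4, -1, 1)))
  blocks <- lapply(1:4, function(i) {
    a <- array(0, c(m, 3))
    a[, , , 2] <- (nodes_true[i] + nodes_true[i + 1]) / 2
    a
  })
  d <- temporal_deconvolve(blocks, reg_weight = 1e-12)
  got <- vapply(d$nodes, function(f) f[1, 1, 1, 2], 0)
  expect_equal(got, nodes_true, tolerance = 1e-6)
})

test_that("deconvolved amplitudes exceed block averages for growing deformation", {
  m <- c(3L, 3L, 2L)
  # monotonically growing saturating deformation, block-averaged
  amp <- function(t) 1 - exp(-3 * t)
  tt <- seq(0, 1, length.out = 5)
  blocks <- lapply(1:4, function(i) {
    a <- array(0, c(m, 3))
    a[, , , 1] <- mean(amp(seq(tt[i], tt[i + 1], length.out = 11)))
    a
  })
  d <- temporal_deconvolve(blocks, reg_weight = 0.1)
  node_amp <- vapply(d$nodes, function(f) f[1, 1, 1, 1], 0)
  block_amp <- vapply(blocks, function(f) f[1, 1, 1, 1], 0)
  expect_gte(max(node_amp), max(block_amp))
  # and the end node counteracts the averaging bias toward the true a(1)
  expect_gt(node_amp[5], 0.9 * amp(1))
})

test_that("flow configuration is validated", {
  expect_error(flow_config(lambda = 2.5), "lambda")
  expect_error(flow_config(lambda = 0), "lambda")
  expect_error(flow_config(kernel_sigma = -1), "kernel_sigma")
  expect_error(flow_config(alpha_rel = 0), "alpha_rel")
  expect_error(flow_config(n_inner = 0), "n_inner")
})
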