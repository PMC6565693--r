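# Deformation-field container: temporal/spatial interpolation, inversion,
# volume warping and upscaling.

test_that("evaluation respects the t = 0 boundary and linear time interpolation", {
  vs <- c(16L, 16L, 8L)
  fld <- array(0, c(vs, 3))
  fld[, , , 1] <- 2
  dvf <- fixture_dvf2(fld)
  pts <- rbind(c(0, 0, 0), c(3.2, -1.5, 1), c(-5, 4, -2))

  expect_equal(dvf_evaluate(dvf, pts, 0), matrix(0, 3, 3))
  # hand linear interpolation: node-1 field (2,0,0), query at t = 0.25
  expect_equal(dvf_evaluate(dvf, pts, 0.25),
               cbind(rep(0.5, 3), 0, 0), tolerance = 1e-12)
  # constant field at all nodes is the identity in time
  dvf2 <- dvf4d(c(0, 0.5, 1), list(array(0, c(vs, 3)), fld, fld), 1L, vs)
  expect_equal(dvf_evaluate(dvf2, pts, 0.75), cbind(rep(2, 3), 0, 0),
               tolerance = 1e-12)

  expect_error(dvf_evaluate(dvf, pts, 1.5), "0, 1")
  expect_equal(nrow(dvf_evaluate(dvf, matrix(0, 0, 3), 0.5)), 0)
})

test_that("evaluation is linear in the node fields and exact at node times", {
  vs <- c(12L, 12L, 8L)
  fld <- fixture_smooth_field(vs, sigma = 3, max_disp = 2, seed = 5)
  dvf <- fixture_dvf2(fld)
  pts <- rbind(c(1.25, -2.5, 0.5), c(-3, 3, -1), c(0, 0, 0))
  a <- 3.7
  dvf_scaled <- fixture_dvf2(a * fld)
  expect_equal(dvf_evaluate(dvf_scaled, pts, 0.6),
               a * dvf_evaluate(dvf, pts, 0.6), tolerance = 1e-12)
  # at node time 1 and at voxel centres (half-integer world coordinates on
  # an even grid), node values are reproduced exactly
  gp <- rbind(c(2.5, 0.5, -1.5))
  ix <- gp[1] + (vs[1] - 1) / 2 + 1
  iy <- gp[2] + (vs[2] - 1) / 2 + 1
  iz <- gp[3] + (vs[3] - 1) / 2 + 1
  expect_equal(as.numeric(dvf_evaluate(dvf, gp, 1)),
               as.numeric(fld[ix, iy, iz, ]), tolerance = 1e-12)
})

test_that("inversion: negate vs fixed point", {
  vs <- c(24L, 24L, 12L)
  pts <- as.matrix(expand.grid(seq(-6, 6, 3), seq(-6, 6, 3), seq(-3, 3, 3)))

  z <- fixture_dvf2(array(0, c(vs, 3)))
  expect_equal(dvf_invert(z, pts, 1, "negate"), matrix(0, nrow(pts), 3))
  expect_equal(dvf_invert(z, pts, 1, "fixed_point"), matrix(0, nrow(pts), 3))

  cst <- array(0, c(vs, 3)); cst[, , , 1] <- 3
  dc <- fixture_dvf2(cst)
  expect_equal(dvf_invert(dc, pts, 1, "fixed_point", 5),
               cbind(rep(-3, nrow(pts)), 0, 0), tolerance = 1e-12)

  sm <- fixture_smooth_field(vs, sigma = 6, max_disp = 2, seed = 3)
  dsm <- fixture_dvf2(sm)
  resid <- function(v) {
    g <- dvf_evaluate(dsm, pts + v, 1)
    sqrt(mean(rowSums((v + g)^2)))
  }
  r_fp <- resid(dvf_invert(dsm, pts, 1, "fixed_point", 5))
  r_ng <- resid(dvf_invert(dsm, pts, 1, "negate"))
  expect_lt(r_fp, r_ng)
})

test_that("warp_volume: identity, integer shifts and round trips", {
  vs <- c(24L, 24L, 16L)
  vol <- fixture_blob(vs)
  z <- fixture_dvf2(array(0, c(vs, 3)))
  expect_identical(warp_volume(vol, z, 0), vol)   # bit-exact identity

  # pull-back by (0,0,2): output(x) = vol(x + 2 e_z), i.e. content moves -z
  cst <- array(0, c(vs, 3)); cst[, , , 3] <- 2
  w <- warp_volume(vol, fixture_dvf2(cst), 1)
  expect_equal(w[, , 1:(vs[3] - 2)], vol[, , 3:vs[3]], tolerance = 1e-12)
  expect_true(all(w[, , (vs[3] - 1):vs[3]] == 0))

  sm <- fixture_smooth_field(vs, sigma = 6, max_disp = 2, seed = 4)
  dsm <- fixture_dvf2(sm)
  rt <- warp_volume(warp_volume(vol, dsm, 1, "forward"), dsm, 1, "inverse")
  interior <- 5:(vs[1] - 4)
  rms <- sqrt(mean((rt[interior, interior, 5:(vs[3] - 4)] -
                    vol[interior, interior, 5:(vs[3] - 4)])^2))
  expect_lt(rms, 0.05 * diff(range(vol)))

  expect_error(warp_volume(array(0, c(8, 8, 8)), dsm, 1), "shape")
})

test_that("upscaling preserves constants and linear ramps", {
  vs <- c(16L, 16L, 8L)
  m <- vs / 2L
  cst <- array(0, c(m, 3)); cst[, , , 2] <- 1.5
  up <- upscale_dvf(fixture_dvf2(cst, 2L, vs))
  expect_equal(up$spatial_step, 1L)
  inner <- 3:(vs[1] - 2)
  expect_equal(up$nodes[[2]][inner, inner, 3:6, 2],
               array(1.5, c(length(inner), length(inner), 4)),
               tolerance = 1e-12)

  # linear ramp in x is reproduced exactly by trilinear interpolation
  ramp <- array(0, c(m, 3))
  xs <- 2 * ((seq_len(m[1]) - 1) - (m[1] - 1) / 2)  # world x of coarse grid
  ramp[, , , 1] <- array(rep(0.1 * xs, prod(m[2:3])), m)
  upr <- upscale_dvf(fixture_dvf2(ramp, 2L, vs))
  xf <- (seq_len(vs[1]) - 1) - (vs[1] - 1) / 2
  expect_equal(upr$nodes[[2]][inner, 8, 4, 1], 0.1 * xf[inner],
               tolerance = 1e-9)

  d1 <- fixture_dvf2(ramp, 1L, m)
  expect_identical(upscale_dvf(d1, 1L), d1)
})

test_that("constructor enforces the container invariants", {
  vs <- c(8L, 8L, 8L)
  z <- array(0, c(vs, 3))
  f <- z; f[, , , 1] <- 1
  expect_error(dvf4d(c(0, 1), list(f, f), 1L, vs), "identically zero")
  expect_error(dvf4d(c(0.1, 1), list(z, f), 1L, vs), "t = 0")
  expect_error(dvf4d(c(0, 1, 0.5), list(z, f, f), 1L, vs), "increasing")
  nan <- f; nan[1, 1, 1, 1] <- NaN
  expect_error(dvf4d(c(0, 1), list(z, nan), 1L, vs), "finite")
})
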