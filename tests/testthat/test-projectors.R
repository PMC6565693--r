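# Straight and curved parallel-beam projector pair.

test_that("forward projection reproduces analytic line integrals", {
  # zero volume
  z <- forward_project(array(0, c(16, 16, 8)), c(0, 1))
  expect_true(all(z$images == 0))

  # single unit voxel at the centre: total projection mass is 1.  Exact for
  # axis-aligned rays; at oblique angles the bilinear footprint sampled on
  # the oblique ray lattice leaves a few-percent phase-dependent residual.
  v <- array(0, c(33, 33, 17)); v[17, 17, 9] <- 1
  for (a in c(0, pi / 2)) {
    p <- forward_project(v, a)
    expect_equal(sum(p$images), 1, tolerance = 1e-6)
  }
  for (a in c(0.4, pi / 4, 1.0)) {
    p <- forward_project(v, a)
    expect_equal(sum(p$images), 1, tolerance = 0.05)
  }

  # uniform unit cylinder: central ray value is the chord length 2R
  R <- 20
  cyl <- fixture_cylinder(64, 32, R)
  p <- forward_project(cyl, c(0, pi / 5))
  # detector column i (1-based) sits at u = i - 1 - (nu - 1)/2
  u_mid <- 33 - 1 - 31.5
  expect_equal(p$images[33, 16, 1], 2 * sqrt(R^2 - u_mid^2),
               tolerance = 0.02 * 2 * R)
  # off-centre ray at distance u: chord 2 sqrt(R^2 - u^2)
  u_off <- 43 - 1 - 31.5
  expect_equal(p$images[43, 16, 1], 2 * sqrt(R^2 - u_off^2),
               tolerance = 0.02 * 2 * R)

  # mass conservation at an oblique angle
  expect_equal(sum(p$images[, , 2]), sum(cyl), tolerance = 0.02 * sum(cyl))
})

test_that("straight projector and backprojector are exact adjoints", {
  set.seed(1)
  vs <- c(32L, 32L, 16L)
  x <- array(rnorm(prod(vs)), vs)
  ang <- seq(0, pi, length.out = 9)[1:8]
  y <- array(rnorm(32 * 16 * 8), c(32, 16, 8))
  Ax <- forward_project(x, ang)$images
  Aty <- back_project(projection_stack(y, ang), vs)$data
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-6)

  expect_true(all(back_project(projection_stack(array(0, c(32, 16, 4)),
                                                ang[1:4]), vs)$data == 0))
})

test_that("a single detector pixel backprojects onto one ray only", {
  vs <- c(32L, 32L, 16L)
  p <- array(0, c(32, 16, 1)); p[10, 8, 1] <- 1
  b <- back_project(projection_stack(p, pi / 2), vs)$data
  nz <- which(b != 0, arr.ind = TRUE)
  # ray along y at angle pi/2: support is one or two x columns, all y, one z
  expect_lte(diff(range(nz[, 1])), 2)
  expect_lte(diff(range(nz[, 3])), 2)
  expect_gt(diff(range(nz[, 2])), 25)
})

test_that("curved operators with zero DVF are bit-identical to straight ones", {
  set.seed(2)
  vs <- c(24L, 24L, 12L)
  x <- array(rnorm(prod(vs)), vs)
  ang <- seq(0, pi, length.out = 7)[1:6]
  tt <- (0:5) / 5
  z <- dvf_zero(vs, 2)
  expect_identical(forward_project(x, ang, dvf = z, times = tt)$images,
                   forward_project(x, ang)$images)
  y <- array(rnorm(24 * 12 * 6), c(24, 12, 6))
  st <- projection_stack(y, ang, tt)
  expect_identical(back_project(st, vs, dvf = z)$data,
                   back_project(st, vs)$data)
})

test_that("constant displacement along the ray leaves line integrals unchanged", {
  vs <- c(32L, 32L, 16L)
  vol <- fixture_blob(vs, sigma = 4)
  cst <- array(0, c(vs, 3)); cst[, , , 2] <- 2.5  # displacement along +y
  dvf <- fixture_dvf2(cst)
  # at angle pi/2 the ray direction is (0, 1, 0): same direction as the shift
  p0 <- forward_project(vol, pi / 2)$images
  p1 <- forward_project(vol, pi / 2, dvf = dvf, times = 1)$images
  expect_lt(max(abs(p1 - p0)), 1e-3 * max(abs(p0)))
})

test_that("constant vertical displacement shifts the projection in v", {
  vs <- c(32L, 32L, 16L)
  vol <- fixture_blob(vs, sigma = 4)
  cst <- array(0, c(vs, 3)); cst[, , , 3] <- 2  # pull-back by +2 in z
  dvf <- fixture_dvf2(cst)
  for (a in c(0, 0.7)) {
    pc <- forward_project(vol, a, dvf = dvf, times = 1)$images[, , 1]
    # pull-back by +2 moves content to -z, i.e. the projection shifts by -2 in v
    ps <- forward_project(vol, a)$images[, , 1]
    expect_equal(pc[, 1:(16 - 2)], ps[, 3:16], tolerance = 1e-6 * max(ps))
  }
})

test_that("curved adjointness: exact for rigid fields, close for smooth ones", {
  set.seed(1)
  vs <- c(32L, 32L, 16L)
  x <- array(rnorm(prod(vs)), vs)
  ang <- seq(0, pi, length.out = 9)[1:8]
  tt <- (0:7) / 7
  y <- array(rnorm(32 * 16 * 8), c(32, 16, 8))
  st <- projection_stack(y, ang, tt)

  cst <- array(0, c(vs, 3)); cst[, , , 1] <- 1.3; cst[, , , 3] <- -0.8
  dc <- fixture_dvf2(cst)
  Ax <- forward_project(x, ang, dvf = dc, times = tt)$images
  Aty <- back_project(st, vs, dvf = dc)$data
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-6)

  # positive test vectors so the pairing does not cancel to a small number
  vs2 <- c(48L, 48L, 24L)
  x2 <- array(abs(rnorm(prod(vs2))), vs2)
  y2 <- array(abs(rnorm(48 * 24 * 8)), c(48, 24, 8))
  sm <- fixture_smooth_field(vs2, sigma = 10, max_disp = 3, seed = 2)
  dsm <- fixture_dvf2(sm)
  st2 <- projection_stack(y2, ang, tt)
  Ax2 <- forward_project(x2, ang, dvf = dsm, times = tt)$images
  Aty2 <- back_project(st2, vs2, dvf = dsm)$data
  lhs <- sum(Ax2 * y2); rhs <- sum(x2 * Aty2)
  expect_lt(abs(lhs - rhs) / abs(lhs), 0.05)
})

test_that("stack metadata is validated", {
  img <- array(0, c(8, 8, 3))
  expect_error(projection_stack(img, c(0, 1)), "match")
  expect_error(projection_stack(img, c(0, 1, 2), times = c(0, 2, 1)), "\\[0, 1\\]")
  expect_error(projection_stack(img, c(0, 1, 2), times = c(0.5, 0.2, 1)),
               "nondecreasing")
  expect_error(projection_stack(img, c(0, 2, 5)), "half turn")
})
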