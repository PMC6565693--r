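# FBP and SIRT solvers, sub-tomogram reconstruction, joint loop basics.

test_that("FBP reconstructs a static cylinder to within 3% inside", {
  expect_true(all(fbp(projection_stack(array(0, c(16, 8, 4)),
                                       seq(0, pi, length.out = 5)[1:4]),
                      c(16, 16, 8))$data == 0))

  R <- 20
  cyl <- fixture_cylinder(64, 32, R)
  ang <- seq(0, pi, length.out = 181)[1:180]
  proj <- forward_project(cyl, ang)
  rec <- fbp(proj, dim(cyl))
  x <- (1:64 - 1) - 31.5
  interior <- array(rep(outer(x^2, x^2, `+`) <= (R - 4)^2, 32), dim(cyl))
  interior[, , c(1:3, 30:32)] <- FALSE
  expect_equal(mean(rec$data[interior]), 1, tolerance = 0.03)
  expect_lt(sd(rec$data[interior]), 0.05)
})

test_that("SIRT converges on noiseless data and preserves zero", {
  # band-limited phantom: a binary target keeps irreducible null-space
  # content at this angular sampling, which iteration count cannot remove
  cfg <- sim_config(shape = c(32, 32, 16), n_angles = 48, n_subtomo = 1,
                    max_disp = 0, seed = 17)
  ph <- make_phantom(cfg)
  ph$data <- gaussian_smooth3(ph$data, 1.5)
  proj <- acquire(ph, NULL, cfg)
  rec <- sirt(proj, dim(ph$data), cfg = recon_config(n_sirt_iters = 100))
  supp <- attr(ph, "support")
  err <- sqrt(sum((rec$data[supp] - ph$data[supp])^2)) /
         sqrt(sum(ph$data[supp]^2))
  expect_lt(err, 0.05)
  # data-fit monotonicity in the noiseless case
  mis <- attr(rec, "misfit")
  expect_true(all(diff(mis) <= 1e-9 * mis[1]))

  z <- sirt(projection_stack(array(0, c(16, 8, 4)),
                             seq(0, pi, length.out = 5)[1:4]),
            c(16, 16, 8), cfg = recon_config(n_sirt_iters = 5))
  expect_true(all(z$data == 0))
})

test_that("sub-tomogram reconstructions agree for a static sample", {
  cfg <- sim_config(shape = c(48, 48, 24), n_angles = 96, n_subtomo = 4,
                    max_disp = 0, seed = 19)
  ph <- make_phantom(cfg)
  proj <- acquire(ph, NULL, cfg)
  rec <- reconstruct_subtomograms(proj, dim(ph$data))
  expect_length(rec$sub, 4)
  # pairwise FSC between interleaved sub-reconstructions stays above the
  # 1/2-bit threshold up to at least 0.25 cycles/px
  f <- fsc(rec$sub[[1]], rec$sub[[3]])
  rf <- attr(f, "resolution_freq")
  expect_true(is.na(rf) || rf >= 0.25)

  # a single sub-tomogram equals the full reconstruction
  cfg1 <- sim_config(shape = c(32, 32, 16), n_angles = 16, n_subtomo = 1,
                     max_disp = 0, seed = 19)
  ph1 <- make_phantom(cfg1)
  p1 <- acquire(ph1, NULL, cfg1)
  r1 <- reconstruct_subtomograms(p1, dim(ph1$data))
  expect_equal(r1$sub[[1]]$data, r1$full$data, tolerance = 1e-12)
})

test_that("the true DVF restores sub-tomogram consistency on deformed data", {
  cfg <- sim_config(shape = c(48, 48, 24), n_angles = 64, n_subtomo = 4,
                    max_disp = 3, spatial_period = 20, seed = 23)
  ph <- make_phantom(cfg)
  mod <- make_dvf_model(cfg)
  proj <- acquire(ph, mod, cfg)
  dtrue <- dvf_model_nodes(mod)

  rec0 <- reconstruct_subtomograms(proj, dim(ph$data))
  rec1 <- reconstruct_subtomograms(proj, dim(ph$data), dvf = dtrue)
  prms <- function(r) {
    s <- r$sub; acc <- c()
    for (i in 1:3) for (j in (i + 1):4)
      acc <- c(acc, sqrt(mean((s[[i]]$data - s[[j]]$data)^2)))
    mean(acc)
  }
  expect_gt(prms(rec0), prms(rec1))

  # FBP through the true DVF beats the uncompensated FBP at low frequency
  f0 <- fsc(fbp(proj, dim(ph$data)), ph)
  f1 <- fsc(fbp(proj, dim(ph$data), dvf = dtrue), ph)
  lo <- f0$freq < 0.3
  expect_true(all(f1$correlation[lo] >= f0$correlation[lo]))

  expect_error(reconstruct_subtomograms(
    projection_stack(array(0, c(8, 4, 0)), numeric(0)), c(8, 8, 4)))
})

test_that("binning block-averages images and rescales shifts", {
  set.seed(31)
  img <- array(rnorm(16 * 8 * 2), c(16, 8, 2))
  st <- projection_stack(img, c(0, 1), shifts = matrix(c(2, -4, 1, 3), 2))
  b <- bin_projections(st, 2)
  expect_equal(dim(b$images), c(8, 4, 2))
  # value convention: block mean divided by the binning factor
  expect_equal(b$images[1, 1, 1], mean(img[1:2, 1:2, 1]) / 2, tolerance = 1e-12)
  expect_equal(b$shifts, st$shifts / 2)
  expect_error(bin_projections(st, 3), "divide")
})

test_that("joint loop on a deformed simulation improves the DVF estimate", {
  cfg <- sim_config(shape = c(48, 48, 24), n_angles = 64, n_subtomo = 4,
                    max_disp = 3, spatial_period = 20, seed = 29)
  ph <- make_phantom(cfg)
  mod <- make_dvf_model(cfg)
  proj <- acquire(ph, mod, cfg)
  sch <- acquisition_scheme(cfg$n_angles, cfg$n_subtomo)
  dtrue <- dvf_model_nodes(mod)
  supp <- nctomo:::study_support_mask(ph, cfg)
  fl <- flow_config(binning = 2L)

  fit0 <- joint_optimize(proj, sch, recon_config(n_joint_iters = 0,
                                                 n_sirt_iters = 0,
                                                 align = FALSE), fl,
                         vol_shape = cfg$shape)
  fit <- joint_optimize(proj, sch, recon_config(n_joint_iters = 12,
                                                n_sirt_iters = 30,
                                                align = FALSE), fl,
                        vol_shape = cfg$shape)
  e0 <- dvf_rms_error(fit0$dvf, dtrue, mask = supp)
  e1 <- dvf_rms_error(fit$dvf, dtrue, mask = supp)
  expect_lt(e1, 0.7 * e0)

  # sub-tomogram mutual consistency improves over the early iterations
  sr <- fit$diagnostics$subtomo_rms
  expect_lt(mean(tail(sr, 3)), mean(head(sr, 2)))

  # the nonrigid model fits the deformed data better than the static one
  pl <- nctomo:::dvf_projection_plan(fit$dvf_coarse, proj$times, 1L)
  sim_n <- nctomo:::project_with_plan(fit$volume$data, proj$angles,
                                      dim(proj$images)[1],
                                      dim(proj$images)[2], 0.5, pl)
  stat <- sirt(proj, cfg$shape, cfg = recon_config(n_sirt_iters = 30))
  sim_s <- nctomo:::project_with_plan(stat$data, proj$angles,
                                      dim(proj$images)[1],
                                      dim(proj$images)[2], 0.5, NULL)
  expect_lt(sqrt(sum((sim_n - proj$images)^2)),
            sqrt(sum((sim_s - proj$images)^2)))
})
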