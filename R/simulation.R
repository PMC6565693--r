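# Numerical experiment generator: porous pillar phantom, smooth random DVF
# with saturating temporal amplitude, interleaved deformed acquisition.

#' Simulation configuration
#'
#' Defaults reproduce a half-scale version of the reference numerical
#' experiment: a porous pillar, a smooth random DVF with saturating
#' amplitude `1 - exp(-3 t)`, and an interleaved half-turn acquisition in
#' four sub-tomograms.
#'
#' @param shape phantom dimensions (nx, ny, nz), voxels.
#' @param n_angles total number of projections over the half turn.
#' @param n_subtomo number of interleaved sub-tomograms.
#' @param max_disp peak displacement magnitude of the DVF at t = 1, voxels.
#' @param spatial_period characteristic spatial period of the random DVF,
#'   voxels (the generating Gaussian correlation filter has
#'   `sigma = spatial_period / 2`).
#' @param amp_rate exponent of the saturating amplitude law
#'   `a(t) proportional to 1 - exp(-amp_rate * t)`, normalized so a(1) = 1.
#' @param porosity void fraction of the pillar interior.
#' @param pore_sigma Gaussian smoothing length (standard deviation) of the
#'   white-noise field that is thresholded into the pore structure, voxels;
#'   structures are roughly 2-3 times this size across.
#' @param radius_margin gap in voxels between the pillar radius and the
#'   x-y extent, so the deformed sample stays inside the field of view;
#'   default `ceiling(max_disp) + 2`.
#' @param noise_std additive Gaussian detector noise (0 = noiseless).
#' @param seed RNG seed; phantom, DVF and noise draw from seed, seed + 1 and
#'   seed + 2 so each piece is individually reproducible.
#' @return A list of class `nct_sim_config`.
#' @export
sim_config <- function(shape = c(100, 100, 50), n_angles = 160L,
                       n_subtomo = 4L, max_disp = 5, spatial_period = 20,
                       amp_rate = 3, porosity = 0.5, pore_sigma = 2,
                       radius_margin = NULL, noise_std = 0, seed = 1L) {
  stopifnot(max_disp >= 0, length(shape) == 3, porosity >= 0, porosity <= 1)
  if (n_angles %% n_subtomo != 0)
    stop("n_subtomo must divide n_angles")
  if (is.null(radius_margin)) radius_margin <- ceiling(max_disp) + 2
  structure(list(shape = as.integer(shape), n_angles = as.integer(n_angles),
                 n_subtomo = as.integer(n_subtomo), max_disp = max_disp,
                 spatial_period = spatial_period, amp_rate = amp_rate,
                 porosity = porosity, pore_sigma = pore_sigma,
                 radius_margin = radius_margin, noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "nct_sim_config")
}

cylinder_mask <- function(shape, radius) {
  nx <- shape[1]; ny <- shape[2]
  x <- (seq_len(nx) - 1) - (nx - 1) / 2
  y <- (seq_len(ny) - 1) - (ny - 1) / 2
  r2 <- outer(x^2, y^2, `+`)
  array(rep(r2 <= radius^2, shape[3]), shape)
}

#' Porous pillar phantom
#'
#' A binary porous cylinder: Gaussian-smoothed white noise is thresholded at
#' the quantile giving the target porosity and masked by a vertical cylinder
#' in the x-y plane.  Values are exactly 0 (void / air) and 1 (material).
#'
#' @param cfg an [sim_config()].
#' @return An [volume3d()] with attribute `"support"`: the logical cylinder
#'   mask.
#' @export
make_phantom <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  shape <- cfg$shape
  radius <- min(shape[1], shape[2]) / 2 - cfg$radius_margin
  field <- gaussian_smooth3(array(rnorm(prod(shape)), shape), cfg$pore_sigma)
  mask <- cylinder_mask(shape, radius)
  vol <- array(0, shape)
  if (cfg$porosity <= 0) {
    vol[mask] <- 1
  } else {
    thr <- quantile(field[mask], cfg$porosity, names = FALSE)
    vol[mask & field > thr] <- 1
  }
  out <- volume3d(vol)
  attr(out, "support") <- mask
  out
}

#' Ground-truth time-evolving DVF model
#'
#' Spatial part: per component, a band-limited Gaussian random field
#' (white noise convolved with a Gaussian of
#' `sigma = spatial_period / 2`), jointly rescaled so the maximum vector
#' magnitude equals `max_disp`.  Temporal part: amplitude
#' `a(t) = (1 - exp(-amp_rate t)) / (1 - exp(-amp_rate))`, so the
#' deformation vanishes at t = 0 and reaches its peak at t = 1.
#'
#' @param cfg an [sim_config()].
#' @return A list of class `nct_dvf_model` with elements `field`
#'   (`(nx, ny, nz, 3)` array), `amp` (function of t) and `cfg`.
#' @export
make_dvf_model <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  shape <- cfg$shape
  sigma <- cfg$spatial_period / 2
  f <- array(0, c(shape, 3))
  for (c in 1:3)
    f[, , , c] <- gaussian_smooth3(array(rnorm(prod(shape)), shape), sigma)
  mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
  if (cfg$max_disp > 0 && max(mag) > 0) f <- f * (cfg$max_disp / max(mag))
  else f[] <- 0
  rate <- cfg$amp_rate
  structure(list(field = f,
                 amp = function(t) (1 - exp(-rate * t)) / (1 - exp(-rate)),
                 cfg = cfg),
            class = "nct_dvf_model")
}

#' Sample a DVF model at interpolation nodes
#'
#' Evaluates the continuous model at the `n_subtomo + 1` node times (the
#' beginning and end of each sub-tomogram), producing the piecewise-linear
#' [dvf4d()] representation that reconstruction estimates.
#'
#' @param model an [make_dvf_model()] result.
#' @param n_subtomo number of sub-tomograms (default from the model config).
#' @return An [dvf4d()] with `spatial_step = 1`.
#' @export
dvf_model_nodes <- function(model, n_subtomo = model$cfg$n_subtomo) {
  tt <- seq(0, 1, length.out = n_subtomo + 1)
  nodes <- lapply(tt, function(t) model$amp(t) * model$field)
  nodes[[1]][] <- 0
  dvf4d(tt, nodes, 1L, model$cfg$shape)
}

#' Simulate an interleaved deformed acquisition
#'
#' For each acquisition index j the phantom is warped (pull-back) by the
#' model DVF evaluated at the dense time `t_j = j / (n - 1)` — so the ground
#' truth contains intra-sub-tomogram evolution that the node-sampled
#' estimate can only average — and then projected along the straight ray at
#' angle `theta_j` of the interleaved schedule.  Optional Gaussian detector
#' noise and injected per-projection ground-truth shifts (for alignment
#' studies) are applied afterwards.
#'
#' @param phantom an [volume3d()] or array.
#' @param model an [make_dvf_model()] result (or NULL for a static scan).
#' @param cfg an [sim_config()].
#' @param nu,nv detector size (defaults: x and z extent of the phantom).
#' @param ds ray-sampling step.
#' @param true_shifts optional `n x 2` matrix of per-projection shifts to
#'   inject into the measured images; the stack's shift metadata stays zero
#'   (alignment has to recover them) and the truth is stored in attribute
#'   `"true_shifts"`.
#' @return An [projection_stack()] with the schedule's angles, times and
#'   sub-tomogram indices.
#' @export
acquire <- function(phantom, model = NULL, cfg = sim_config(), nu = NULL,
                    nv = NULL, ds = 0.5, true_shifts = NULL) {
  a <- as_vol_array(phantom)
  d <- dim(a)
  if (is.null(nu)) nu <- d[1]
  if (is.null(nv)) nv <- d[3]
  sch <- acquisition_scheme(cfg$n_angles, cfg$n_subtomo)
  np <- nrow(sch)
  img <- array(0, c(nu, nv, np))
  for (j in seq_len(np)) {
    w <- if (is.null(model) || model$amp(sch$time[j]) == 0) a else {
      disp <- model$amp(sch$time[j]) * model$field
      array(cpp_warp(as.numeric(a), d, as.numeric(disp), d, 1), d)
    }
    img[, , j] <- project_with_plan(w, sch$angle[j], nu, nv, ds, NULL)[, , 1]
  }
  if (!is.null(true_shifts)) {
    true_shifts <- matrix(as.numeric(true_shifts), ncol = 2)
    for (j in seq_len(np))
      if (any(true_shifts[j, ] != 0))
        img[, , j] <- cpp_shift_image(img[, , j], true_shifts[j, 1],
                                      true_shifts[j, 2])
  }
  if (cfg$noise_std > 0) {
    set.seed(cfg$seed + 2L)
    img <- img + array(rnorm(length(img), 0, cfg$noise_std), dim(img))
  }
  out <- projection_stack(img, sch$angle, sch$time, sch$subtomo)
  attr(out, "true_shifts") <- true_shifts
  out
}
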