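# Straight- and curved-ray parallel-beam projectors.
#
# The forward operator integrates the volume along rays with direction
# (cos a, sin a, 0); the detector u axis is (-sin a, cos a, 0) and v is the
# rotation axis z.  Rays are sampled Joseph-style at a fixed step `ds`
# (default 0.5 voxel) with trilinear gathering, and the sum is scaled by
# `ds`.  The backprojector is the exact adjoint under the same sampling
# rule: it scatters each measured pixel along its ray with the same weights.
#
# With a DVF the operators are warp-composed: the forward operator projects
# the pull-back-warped volume (out(x) = g(x + Gamma(x, t_j))) along straight
# rays, which evaluates the virtual curved path l + Gamma(l, t_j); the
# transpose backprojects along straight rays and warp-gathers the result
# through the fixed-point inverse displacement, realizing the voxel-driven
# reading of the transposed curved geometry (voxel x is seen by the detector
# at x + Gamma^{-1}(x, t_j)).  With a zero DVF both operators are
# bit-identical to their straight counterparts; for rigid fields the pair is
# exactly adjoint, for smooth fields approximately (the mismatch, of the
# order of the displacement Jacobian, is monitored by the test suite rather
# than corrected).

# Per-projection displacement fields precomputed for a stack: the node
# fields of `dvf` are blended at each projection's time (and inverted by
# fixed point for the backprojection direction), scaled to the working grid.
# `binning` > 1 reconstructs on a grid coarsened by that factor; the DVF
# spatial_step must be a multiple of it.
dvf_projection_plan <- function(dvf, times, binning = 1L, invert = FALSE,
                                n_inv_iter = 5L) {
  if (is.null(dvf)) return(NULL)
  if (dvf$spatial_step %% binning != 0)
    stop("DVF spatial_step must be a multiple of the reconstruction binning")
  m <- dim(dvf$nodes[[1]])[1:3]
  np <- length(times)
  dstep <- dvf$spatial_step / binning
  disp <- array(0, c(m, 3, np))
  for (j in seq_len(np)) {
    d <- dvf_blend(dvf, times[j]) / binning  # working-voxel units
    if (invert)
      d <- cpp_invert_grid(as.numeric(d), m, dstep, as.integer(n_inv_iter))$field
    disp[, , , , j] <- d
  }
  list(disp = disp, mdim = m, dstep = dstep)
}

#' Forward projection (straight or curved rays)
#'
#' Computes line integrals of a volume for a set of projection angles.  When
#' a DVF is supplied each ray is bent through the deformation at that
#' projection's acquisition time, realizing the nonrigid system matrix; with
#' `dvf = NULL` (or an all-zero field) this is the classical straight-ray
#' parallel-beam projector.
#'
#' @param vol an [volume3d()] or 3-D array.
#' @param angles projection angles in radians.
#' @param nu,nv detector size in pixels (defaults: volume x and z extent).
#' @param ds ray sampling step in voxels.
#' @param dvf optional [dvf4d()].
#' @param times normalized acquisition times, one per angle (required with a
#'   DVF).
#' @param shifts optional `n x 2` per-projection detector shifts (du, dv);
#'   the returned images are translated by their shifts (the measured-frame
#'   convention), via bilinear resampling.
#' @param binning reconstruction-grid binning factor relative to the DVF's
#'   full-resolution grid (used by the multiresolution joint loop).
#' @return An [projection_stack()].
#' @export
forward_project <- function(vol, angles, nu = NULL, nv = NULL, ds = 0.5,
                            dvf = NULL, times = NULL, shifts = NULL,
                            binning = 1L) {
  a <- as_vol_array(vol)
  d <- dim(a)
  if (is.null(nu)) nu <- d[1]
  if (is.null(nv)) nv <- d[3]
  np <- length(angles)
  if (!is.null(dvf)) {
    if (is.null(times)) stop("per-projection times are required with a DVF")
    if (length(times) != np) stop("times must match angles")
    plan <- dvf_projection_plan(dvf, times, binning, invert = FALSE)
  } else plan <- NULL
  img <- project_with_plan(a, angles, nu, nv, ds, plan)
  if (!is.null(shifts)) {
    shifts <- matrix(as.numeric(shifts), ncol = 2)
    for (j in seq_len(np))
      if (any(shifts[j, ] != 0))
        img[, , j] <- cpp_shift_image(img[, , j], shifts[j, 1], shifts[j, 2])
  } else shifts <- matrix(0, np, 2)
  projection_stack(img, angles,
                   times = if (is.null(times)) NULL else times,
                   shifts = shifts)
}

project_with_plan <- function(a, angles, nu, nv, ds, plan) {
  if (is.null(plan)) {
    p <- cpp_project(as.numeric(a), dim(a), as.numeric(angles),
                     as.integer(nu), as.integer(nv), ds,
                     NULL, integer(3), 1)
  } else {
    p <- cpp_project(as.numeric(a), dim(a), as.numeric(angles),
                     as.integer(nu), as.integer(nv), ds,
                     as.numeric(plan$disp), plan$mdim, plan$dstep)
  }
  array(p, c(nu, nv, length(angles)))
}

#' Backprojection (straight or curved rays)
#'
#' Adjoint of [forward_project()] under the same ray-sampling rule.  Stored
#' per-projection shifts are compensated (images are resampled back to the
#' ideal detector frame) before scattering.  With a DVF, rays are bent by
#' the fixed-point inverse displacement field at each projection's time.
#'
#' @param proj an [projection_stack()].
#' @param vol_shape integer length-3 output volume shape.
#' @param ds ray sampling step in voxels.
#' @param dvf optional [dvf4d()].
#' @param binning reconstruction-grid binning relative to the DVF grid.
#' @param n_inv_iter fixed-point iterations for the inverse DVF.
#' @return An [volume3d()].
#' @export
back_project <- function(proj, vol_shape, ds = 0.5, dvf = NULL, binning = 1L,
                         n_inv_iter = 5L) {
  plan <- if (is.null(dvf)) NULL
          else dvf_projection_plan(dvf, proj$times, binning, invert = TRUE,
                                   n_inv_iter = n_inv_iter)
  backproject_with_plan(proj, vol_shape, ds, plan)
}

backproject_with_plan <- function(proj, vol_shape, ds, plan) {
  img <- proj$images
  d <- dim(img)
  for (j in seq_len(d[3]))
    if (any(proj$shifts[j, ] != 0))
      img[, , j] <- cpp_shift_image(img[, , j], -proj$shifts[j, 1],
                                    -proj$shifts[j, 2])
  v <- if (is.null(plan)) {
    cpp_backproject(as.numeric(img), d[1], d[2], proj$angles,
                    as.integer(vol_shape), ds, NULL, integer(3), 1)
  } else {
    cpp_backproject(as.numeric(img), d[1], d[2], proj$angles,
                    as.integer(vol_shape), ds,
                    as.numeric(plan$disp), plan$mdim, plan$dstep)
  }
  volume3d(array(v, vol_shape))
}
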