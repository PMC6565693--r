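# Nonrigid FBP and SIRT solvers and the self-consistent joint loop.

#' Reconstruction configuration
#'
#' @param n_joint_iters outer iterations of the joint 3-step loop
#'   (reconstruct, update DVF, refine shifts).
#' @param n_sirt_iters iterations of the final SIRT refinement.
#' @param filter ramp-filter name for FBP: `"ram-lak"` or `"hamming"`.
#' @param nonneg clamp negative voxels after each SIRT iteration.
#' @param relax_sirt SIRT relaxation factor in (0, 2].
#' @param ds ray-sampling step of the projectors, in voxels.
#' @param align refine per-projection shifts inside the joint loop.
#' @param align_step_size damping of the per-iteration shift update:
#'   deformation residuals masquerade as apparent shifts early in the loop,
#'   and a damped update lets the DVF claim them while persistent true
#'   shift errors are still integrated over the iterations.
#' @return A list of class `nct_recon_config`.
#' @export
recon_config <- function(n_joint_iters = 50L, n_sirt_iters = 50L,
                         filter = c("ram-lak", "hamming"), nonneg = FALSE,
                         relax_sirt = 1.0, ds = 0.5, align = TRUE,
                         align_step_size = 0.5) {
  filter <- match.arg(filter)
  stopifnot(n_joint_iters >= 0, n_sirt_iters >= 0,
            relax_sirt > 0, relax_sirt <= 2, align_step_size > 0)
  structure(list(n_joint_iters = as.integer(n_joint_iters),
                 n_sirt_iters = as.integer(n_sirt_iters), filter = filter,
                 nonneg = nonneg, relax_sirt = relax_sirt, ds = ds,
                 align = align, align_step_size = align_step_size),
            class = "nct_recon_config")
}

# 1-D ramp filtering of all projections along the detector u axis, with
# power-of-two zero padding against wrap-around.  The filter is the DFT of
# the band-limited real-space ramp kernel (h[0] = 1/4, h[n] = -1/(pi n)^2
# for odd n), not |f| sampled on the DFT grid: the sampled-|f| shortcut has
# the wrong DC behaviour and biases the interior of reconstructions by
# several percent.
ramp_filter_stack <- function(images, filter = "ram-lak") {
  d <- dim(images)
  nu <- d[1]
  npad <- 2^ceiling(log2(2 * nu))
  n <- c(0:(npad / 2), seq(-(npad / 2 - 1), -1))
  h <- numeric(npad)
  h[1] <- 0.25
  odd <- which(n %% 2 != 0)
  h[odd] <- -1 / (pi * n[odd])^2
  H <- Re(fft(h))
  if (filter == "hamming") {
    f <- n / npad
    H <- H * (0.54 + 0.46 * cos(pi * f / 0.5))
  }
  mat <- matrix(0, npad, d[2] * d[3])
  mat[seq_len(nu), ] <- images
  filt <- Re(mvfft(mvfft(mat) * H, inverse = TRUE)) / npad
  array(filt[seq_len(nu), ], d)
}

#' Filtered back projection (straight or curved geometry)
#'
#' 1-D ramp filtering of each projection along the detector row, followed by
#' (curved) backprojection and scaling by `pi / n_angles`.  With
#' `dvf = NULL` this is the conventional FBP; with a DVF it reconstructs the
#' reference (t = 0) state through the nonrigid geometry.  Stored
#' per-projection shifts are compensated during backprojection.
#'
#' @param proj an [projection_stack()].
#' @param vol_shape integer length-3 output shape.
#' @param dvf optional [dvf4d()].
#' @param filter `"ram-lak"` (default) or `"hamming"`.
#' @param ds ray-sampling step in voxels.
#' @param binning reconstruction-grid binning relative to the DVF grid.
#' @return An [volume3d()].
#' @export
fbp <- function(proj, vol_shape, dvf = NULL, filter = "ram-lak", ds = 0.5,
                binning = 1L) {
  plan <- if (is.null(dvf)) NULL
          else dvf_projection_plan(dvf, proj$times, binning, invert = TRUE)
  fbp_with_plan(proj, vol_shape, plan, filter, ds)
}

fbp_with_plan <- function(proj, vol_shape, plan, filter, ds) {
  fp <- proj
  fp$images <- ramp_filter_stack(proj$images, filter)
  v <- backproject_with_plan(fp, vol_shape, ds, plan)
  volume3d(v$data * pi / length(proj$angles))
}

#' SIRT reconstruction (straight or curved geometry)
#'
#' Simultaneous iterative reconstruction: preconditioned gradient iteration
#' `g <- g + relax * C (A^T (R (p - A g)))` on the least-squares data misfit,
#' where R and C are the inverse row- and column-sum weightings of the
#' straight-geometry operator.  With a DVF the forward and transpose
#' operators follow the curved virtual paths.
#'
#' @param proj an [projection_stack()].
#' @param vol_shape integer length-3 output shape.
#' @param dvf optional [dvf4d()].
#' @param cfg an [recon_config()]; uses `n_sirt_iters`, `relax_sirt`,
#'   `nonneg`, `ds`.
#' @param init optional initial volume (default zero).
#' @param binning reconstruction-grid binning relative to the DVF grid.
#' @return An [volume3d()] with attribute `"misfit"`: the data-misfit norm
#'   `||A g - p||` per iteration.
#' @export
sirt <- function(proj, vol_shape, dvf = NULL, cfg = recon_config(),
                 init = NULL, binning = 1L) {
  d <- dim(proj$images)
  nu <- d[1]; nv <- d[2]; np <- d[3]
  ds <- cfg$ds
  fwd_plan <- bwd_plan <- NULL
  if (!is.null(dvf)) {
    fwd_plan <- dvf_projection_plan(dvf, proj$times, binning, invert = FALSE)
    bwd_plan <- dvf_projection_plan(dvf, proj$times, binning, invert = TRUE)
  }
  # shift-compensated data (ideal detector frame)
  p <- proj$images
  for (j in seq_len(np))
    if (any(proj$shifts[j, ] != 0))
      p[, , j] <- cpp_shift_image(p[, , j], -proj$shifts[j, 1],
                                  -proj$shifts[j, 2])
  data_stack <- projection_stack(p, proj$angles, proj$times, proj$subtomo)

  # inverse row/column sums of the straight operator
  ones_v <- array(1, vol_shape)
  rs <- project_with_plan(ones_v, proj$angles, nu, nv, ds, NULL)
  ones_p <- projection_stack(array(1, d), proj$angles, proj$times, proj$subtomo)
  cs <- backproject_with_plan(ones_p, vol_shape, ds, NULL)$data
  Rw <- ifelse(rs > 1e-6 * max(rs), 1 / rs, 0)
  Cw <- ifelse(cs > 1e-6 * max(cs), 1 / cs, 0)

  g <- if (is.null(init)) array(0, vol_shape) else as_vol_array(init)
  misfit <- numeric(cfg$n_sirt_iters)
  for (it in seq_len(cfg$n_sirt_iters)) {
    sim <- project_with_plan(g, proj$angles, nu, nv, ds, fwd_plan)
    r <- p - sim
    misfit[it] <- sqrt(sum(r^2))
    upd <- backproject_with_plan(
      projection_stack(r * Rw, proj$angles, proj$times, proj$subtomo),
      vol_shape, ds, bwd_plan)$data
    g <- g + cfg$relax_sirt * Cw * upd
    if (cfg$nonneg) g[g < 0] <- 0
  }
  out <- volume3d(g)
  attr(out, "misfit") <- misfit
  out
}

#' Reconstruct the full tomogram and all sub-tomograms
#'
#' One nonrigid FBP per sub-tomogram (using only its projections) plus the
#' full reconstruction from all projections.  All reconstructions are
#' backprojected through the current DVF estimate, so every sub-tomogram
#' lives in the common reference (t = 0) frame and residual differences
#' between them measure only the remaining DVF error.
#'
#' @inheritParams fbp
#' @return A list with elements `full` (an [volume3d()]) and `sub` (list of
#'   [volume3d()], one per sub-tomogram in acquisition order).
#' @export
reconstruct_subtomograms <- function(proj, vol_shape, dvf = NULL,
                                     filter = "ram-lak", ds = 0.5,
                                     binning = 1L) {
  ids <- sort(unique(proj$subtomo))
  counts <- table(proj$subtomo)
  if (any(counts == 0)) stop("empty sub-tomogram")
  plan <- if (is.null(dvf)) NULL
          else dvf_projection_plan(dvf, proj$times, binning, invert = TRUE)
  full <- fbp_with_plan(proj, vol_shape, plan, filter, ds)
  sub <- lapply(ids, function(i) {
    idx <- which(proj$subtomo == i)
    spl <- if (is.null(plan)) NULL else {
      list(disp = plan$disp[, , , , idx, drop = FALSE], mdim = plan$mdim,
           dstep = plan$dstep)
    }
    # rescale: FBP normalization uses the subset's own angle count
    fbp_with_plan(subset_stack(proj, idx), vol_shape, spl, filter, ds)
  })
  list(full = full, sub = sub)
}

#' Joint reconstruction of volume, 4-D DVF and projection shifts
#'
#' The self-consistent nonrigid reconstruction loop.  Each outer iteration
#' performs three steps: (1) nonrigid FBP of the full tomogram and of every
#' sub-tomogram under the current DVF and shifts; (2) a 3-D optical-flow
#' update of each sub-tomogram's block DVF from the (full, sub) volume pair,
#' followed by Tikhonov temporal deconvolution onto the interpolation
#' nodes (the t = 0 node stays zero); (3) projection-matching refinement of
#' the per-projection detector shifts.  DVF estimation runs on a grid
#' coarsened by `flow_cfg$binning` (the flow kernel is rescaled
#' accordingly); afterwards the DVF is upscaled and the final volume is
#' refined by `cfg$n_sirt_iters` of nonrigid SIRT at full resolution,
#' initialized from the nonrigid FBP.
#'
#' Because the reference state is pinned at t = 0, the returned volume
#' approximates the sample at the beginning of the acquisition.
#'
#' @param proj an [projection_stack()] with times and sub-tomogram indices.
#' @param scheme optional [acquisition_scheme()] (only needed for exact
#'   block time-averaging in the deconvolution).
#' @param cfg an [recon_config()].
#' @param flow_cfg an [flow_config()].
#' @param vol_shape reconstruction shape; default `(nu, nu, nv)`.
#' @param verbose print per-iteration diagnostics.
#' @return A list: `volume` (final [volume3d()]), `dvf` (full-resolution
#'   [dvf4d()]), `dvf_coarse` (the estimation-grid DVF), `shifts`
#'   (per-projection matrix), and `diagnostics` (data.frame with
#'   per-iteration reprojection misfit and mean pairwise RMS between
#'   sub-tomogram reconstructions).  If the misfit grows to twice its
#'   running minimum the loop stops early with a warning and the best
#'   iterate is returned.
#' @export
joint_optimize <- function(proj, scheme = NULL, cfg = recon_config(),
                           flow_cfg = flow_config(), vol_shape = NULL,
                           verbose = FALSE) {
  d <- dim(proj$images)
  if (is.null(vol_shape)) vol_shape <- c(d[1], d[1], d[2])
  vol_shape <- as.integer(vol_shape)
  b <- flow_cfg$binning
  ids <- sort(unique(proj$subtomo))
  N <- length(ids)
  shape_b <- vol_shape %/% b
  stack_b <- bin_projections(proj, b)
  shifts <- proj$shifts
  dvf <- dvf_zero(vol_shape, N, spatial_step = b)
  misfit_hist <- pair_hist <- numeric(0)
  best <- list(misfit = Inf, dvf = dvf, shifts = shifts)
  diverged <- FALSE

  for (it in seq_len(cfg$n_joint_iters)) {
    stk <- stack_b
    stk$shifts <- shifts / b
    rec <- reconstruct_subtomograms(stk, shape_b, dvf, cfg$filter, cfg$ds,
                                    binning = b)
    gF <- rec$full$data
    # shift refinement + reprojection misfit, under the same model state
    # (volume and DVF) that produced the reconstructions
    al <- align_step(stk, shifts / b, rec$full, dvf, cfg, b,
                     update = cfg$align, step_size = cfg$align_step_size,
                     remove_drift = TRUE)
    if (cfg$align) shifts <- al$shifts * b
    # block DVF update + temporal deconvolution.  The sub-reconstructions
    # are already mapped through the current DVF, so the flow estimates only
    # the residual displacement of each g^(i) relative to g^F (pull-back:
    # g^(i)(x) ~ g^F(x + delta)), which is the convergent orientation under
    # the curved-operator conventions; gradients are taken on the sharper
    # full reconstruction.
    updates <- vector("list", N)
    for (i in seq_len(N))
      updates[[i]] <- flow_residual_estimate(gF, rec$sub[[i]]$data,
                                             flow_cfg) * b
    dvf <- deconvolve_increment(dvf, updates, flow_cfg$reg_weight)
    misfit_hist <- c(misfit_hist, al$misfit)
    pair_hist <- c(pair_hist, mean_pairwise_rms(rec$sub))
    if (verbose)
      message(sprintf("joint iter %3d: misfit %.5g, sub-tomogram RMS %.5g",
                      it, al$misfit, pair_hist[it]))
    if (al$misfit < best$misfit)
      best <- list(misfit = al$misfit, dvf = dvf, shifts = shifts)
    if (al$misfit > 2 * min(misfit_hist)) {
      warning("joint optimization diverging; returning best iterate")
      dvf <- best$dvf
      shifts <- best$shifts
      diverged <- TRUE
      break
    }
  }

  # final full-resolution reconstruction with the converged DVF
  stk_full <- proj
  stk_full$shifts <- shifts
  g0 <- fbp(stk_full, vol_shape, dvf, cfg$filter, cfg$ds)
  g <- if (cfg$n_sirt_iters > 0)
    sirt(stk_full, vol_shape, dvf, cfg, init = g0)
  else g0
  list(volume = g, dvf = upscale_dvf(dvf), dvf_coarse = dvf, shifts = shifts,
       diagnostics = data.frame(iter = seq_along(misfit_hist),
                                misfit = misfit_hist,
                                subtomo_rms = pair_hist),
       diverged = diverged)
}

mean_pairwise_rms <- function(vols) {
  n <- length(vols)
  if (n < 2) return(0)
  acc <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- acc + sqrt(mean((vols[[i]]$data - vols[[j]]$data)^2))
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Bin a projection stack
#'
#' Block-averages each image by an integer factor and rescales the stored
#' shifts; values are divided by the factor so that binned projections match
#' line integrals of the block-averaged volume measured in binned voxel
#' units.
#'
#' @param proj an [projection_stack()].
#' @param b integer binning factor (must divide the detector size).
#' @return An [projection_stack()].
#' @export
bin_projections <- function(proj, b) {
  if (b == 1) return(proj)
  d <- dim(proj$images)
  if (d[1] %% b != 0 || d[2] %% b != 0)
    stop("binning must divide the detector dimensions")
  out <- array(0, c(d[1] / b, d[2] / b, d[3]))
  for (i in seq_len(b)) for (j in seq_len(b))
    out <- out + proj$images[seq(i, d[1], by = b), seq(j, d[2], by = b), ,
                             drop = FALSE]
  projection_stack(out / (b * b * b), proj$angles, proj$times, proj$subtomo,
                   proj$shifts / b)
}
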