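# Projection-matching alignment: per-projection rigid shift estimation
# against reprojections of the current (nonrigid) tomography model.

grad2d_u <- function(m) {
  n <- nrow(m)
  g <- matrix(0, n, ncol(m))
  if (n < 2) return(g)
  if (n >= 3) g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[n, ] <- m[n, ] - m[n - 1, ]
  g
}

# single global (du, dv) between a measured and a reprojected image:
# 2-D optical flow reduced to its weighted mean over a support mask,
# iterated as a gradient descent on the shift
estimate_shift <- function(meas, reproj, n_iter = 5L, step_size = 1.0,
                           mask_frac = 0.05) {
  mask <- reproj > mask_frac * max(reproj)
  if (!any(mask)) return(c(0, 0))
  gu <- grad2d_u(reproj)
  gv <- t(grad2d_u(t(reproj)))
  du2 <- sum(gu[mask]^2); dv2 <- sum(gv[mask]^2)
  if (du2 == 0 && dv2 == 0) return(c(0, 0))
  sh <- c(0, 0)
  for (k in seq_len(n_iter)) {
    a <- cpp_shift_image(meas, -sh[1], -sh[2])  # align with current estimate
    r <- a - reproj
    if (du2 > 0) sh[1] <- sh[1] - step_size * sum((r * gu)[mask]) / du2
    if (dv2 > 0) sh[2] <- sh[2] - step_size * sum((r * gv)[mask]) / dv2
  }
  sh
}

#' Refine per-projection shifts by projection matching
#'
#' For each projection the current volume is reprojected through the
#' nonrigid model at that projection's angle and time; a single global
#' (du, dv) displacement of the measured image with respect to the
#' reprojection is then estimated by 2-D optical flow averaged over a
#' support mask (pixels where the reprojection exceeds 5% of its maximum),
#' iterated `n_iter` times, and added to the stored shifts.
#'
#' @param proj an [projection_stack()]; stored shifts are the current
#'   estimates.
#' @param vol current reconstruction ([volume3d()] or array).
#' @param dvf optional [dvf4d()] for the reprojection geometry.
#' @param step_size gradient-descent step on the shift.
#' @param n_iter flow iterations per projection.
#' @param binning reconstruction-grid binning relative to the DVF grid.
#' @return The stack with updated `shifts`.  If the volume is blank the
#'   shifts are returned unchanged with a warning.
#' @export
refine_shifts <- function(proj, vol, dvf = NULL, step_size = 1.0,
                          n_iter = 5L, binning = 1L) {
  a <- as_vol_array(vol)
  if (all(a == 0)) {
    warning("blank reprojection volume; shifts unchanged")
    return(proj)
  }
  st <- align_step(proj, proj$shifts, volume3d(a), dvf,
                   recon_config(ds = 0.5), binning, update = TRUE,
                   n_iter = n_iter, step_size = step_size)
  out <- proj
  out$shifts <- st$shifts
  out
}

# Remove the rigid-translation (gauge) component from per-projection
# shifts: for parallel geometry a global object translation (tx, ty, tz)
# appears as du = -tx sin(a) + ty cos(a), dv = tz, which is degenerate with
# moving the reconstruction itself.  Projecting it out pins the volume's
# position and keeps the self-consistent loop from drifting.
remove_shift_drift <- function(shifts, angles) {
  B <- cbind(-sin(angles), cos(angles))
  fit <- B %*% qr.solve(B, shifts[, 1])
  shifts[, 1] <- shifts[, 1] - fit
  shifts[, 2] <- shifts[, 2] - mean(shifts[, 2])
  shifts
}

# shared with the joint loop: reproject, optionally update shifts, and
# report the reprojection misfit of the aligned measured images
align_step <- function(proj, shifts, vol, dvf, cfg, binning, update = TRUE,
                       n_iter = 1L, step_size = 1.0, remove_drift = FALSE) {
  d <- dim(proj$images)
  reproj <- forward_project(vol$data, proj$angles, d[1], d[2], cfg$ds,
                            dvf = dvf, times = proj$times, binning = binning)
  new_shifts <- shifts
  if (update) {
    for (j in seq_len(d[3])) {
      rj <- reproj$images[, , j]
      if (!any(rj != 0)) next
      aligned <- cpp_shift_image(proj$images[, , j],
                                 -shifts[j, 1], -shifts[j, 2])
      inc <- estimate_shift(aligned, rj, n_iter = n_iter)
      new_shifts[j, ] <- shifts[j, ] + step_size * inc
    }
    if (remove_drift) new_shifts <- remove_shift_drift(new_shifts, proj$angles)
  }
  misfit <- 0
  for (j in seq_len(d[3])) {
    aj <- cpp_shift_image(proj$images[, , j],
                          -new_shifts[j, 1], -new_shifts[j, 2])
    misfit <- misfit + sum((aj - reproj$images[, , j])^2)
  }
  list(shifts = new_shifts, misfit = sqrt(misfit))
}

#' Resample projections to the ideal detector frame
#'
#' Applies each projection's stored (du, dv) by bilinear resampling, so the
#' returned images are aligned with the ideal (unshifted) geometry, and
#' zeroes the shift metadata.  Borders are zero-filled (the sample is
#' surrounded by air).
#'
#' @param proj an [projection_stack()].
#' @return An [projection_stack()] with zero shifts.
#' @export
apply_shifts <- function(proj) {
  img <- proj$images
  for (j in seq_len(dim(img)[3]))
    if (any(proj$shifts[j, ] != 0))
      img[, , j] <- cpp_shift_image(img[, , j], -proj$shifts[j, 1],
                                    -proj$shifts[j, 2])
  projection_stack(img, proj$angles, proj$times, proj$subtomo, NULL)
}
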