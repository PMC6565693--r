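# Estimation of the discretized sub-tomogram DVFs by 3-D optical flow and
# Tikhonov deconvolution of their time evolution onto interpolation nodes.

#' Optical-flow configuration
#'
#' @param lambda relaxation constant of the flow update; must lie in (0, 2).
#'   The default 1.7 converges noticeably faster than 1 through a wide
#'   smoothing kernel while staying clear of the instability that sets in
#'   close to 2.
#' @param kernel_sigma standard deviation of the isotropic Gaussian
#'   smoothing kernel, in full-resolution voxels (rescaled by `binning` when
#'   estimation runs on a coarsened grid); truncated at 3 sigma.
#' @param alpha_rel stabilization constant, relative to the maximum of the
#'   smoothed squared gradient (makes the update invariant to intensity
#'   units and prevents noise amplification in smooth regions).
#' @param binning spatial downsampling factor of the grid on which the DVF
#'   is estimated.
#' @param reg_weight Tikhonov weight of the temporal-smoothness penalty in
#'   the node deconvolution.
#' @param n_inner inner incremental-warping passes of each flow solve: after
#'   every pass the moving volume is re-warped by the current estimate and
#'   the update is re-linearized, which extends the capture range beyond
#'   sub-voxel displacements; `n_inner = 1` is the classic one-step update.
#' @param n_outer number of joint-loop iterations (used by
#'   [joint_optimize()]).
#' @return A list of class `nct_flow_config`.
#' @export
flow_config <- function(lambda = 1.7, kernel_sigma = 30, alpha_rel = 1e-2,
                        binning = 1L, reg_weight = 0.1, n_inner = 12L,
                        n_outer = 50L) {
  if (lambda <= 0 || lambda >= 2) stop("lambda must lie in (0, 2)")
  if (kernel_sigma <= 0) stop("kernel_sigma must be positive")
  if (alpha_rel <= 0) stop("alpha_rel must be positive")
  if (n_inner < 1) stop("n_inner must be at least 1")
  structure(list(lambda = lambda, kernel_sigma = kernel_sigma,
                 alpha_rel = alpha_rel, binning = as.integer(binning),
                 reg_weight = reg_weight, n_inner = as.integer(n_inner),
                 n_outer = as.integer(n_outer)),
            class = "nct_flow_config")
}

# Estimate the displacement field delta with mov(x) ~ ref(x + delta(x)), by
# Gaussian-smoothed normalized gradient updates with inner incremental
# warping: each pass warps `mov` back by the current delta and adds the
# re-linearized increment.  Gradients and the smoothed squared-gradient
# denominator are taken on `ref` once.  `init` seeds the estimate.
flow_residual_estimate <- function(ref, mov, cfg, init = NULL) {
  d <- dim(ref)
  sigma <- cfg$kernel_sigma / cfg$binning
  delta <- if (is.null(init)) array(0, c(d, 3)) else init
  grads <- lapply(1:3, function(ax) central_gradient(ref, ax))
  dens <- lapply(grads, function(g) gaussian_smooth3(g * g, sigma))
  alphas <- vapply(dens, function(dn) cfg$alpha_rel * max(dn), 0)
  if (all(alphas <= 0)) return(delta)  # featureless reference
  for (k in seq_len(cfg$n_inner)) {
    moved <- if (all(delta == 0)) mov else
      array(cpp_warp(as.numeric(mov), d, as.numeric(-delta), d, 1), d)
    resid <- moved - ref
    for (ax in 1:3) {
      num <- gaussian_smooth3(resid * grads[[ax]], sigma)
      delta[, , , ax] <- delta[, , , ax] +
        cfg$lambda * num / (dens[[ax]] + alphas[ax])
    }
  }
  delta
}

gaussian_kernel1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k / sum(k)
}

#' Gaussian smoothing of a 3-D grid
#'
#' Separable convolution with a normalized Gaussian truncated at 3 sigma
#' (zero boundary).
#'
#' @param a 3-D array.
#' @param sigma standard deviation in voxels.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth3 <- function(a, sigma) {
  array(cpp_conv3_sep(as.numeric(a), dim(a), gaussian_kernel1d(sigma)), dim(a))
}

# central differences in the interior, one-sided at the faces
central_gradient <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  g <- array(0, d)
  if (n < 2) return(g)
  if (axis == 1) {
    if (n >= 3) g[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / 2
    g[1, , ] <- a[2, , ] - a[1, , ]
    g[n, , ] <- a[n, , ] - a[n - 1, , ]
  } else if (axis == 2) {
    if (n >= 3) g[, 2:(n - 1), ] <- (a[, 3:n, ] - a[, 1:(n - 2), ]) / 2
    g[, 1, ] <- a[, 2, ] - a[, 1, ]
    g[, n, ] <- a[, n, ] - a[, n - 1, ]
  } else {
    if (n >= 3) g[, , 2:(n - 1)] <- (a[, , 3:n] - a[, , 1:(n - 2)]) / 2
    g[, , 1] <- a[, , 2] - a[, , 1]
    g[, , n] <- a[, , n] - a[, , n - 1]
  }
  g
}

#' Optical-flow update of a block DVF
#'
#' Gradient-type displacement estimate between two volumes on the same
#' grid.  Per axis j a pass adds
#' `lambda * smooth((g_full - g_sub) * grad_j g_full) /
#'  (smooth((grad_j g_full)^2) + alpha)`,
#' where `smooth` is Gaussian convolution with the configured kernel and
#' `alpha = alpha_rel * max(smoothed squared gradient)`; spatial gradients
#' are central differences.  With `cfg$n_inner > 1` the moving volume is
#' re-warped by the current estimate between passes (incremental warping),
#' which re-linearizes the update and extends the capture range beyond
#' sub-voxel displacements; a single pass is the classic one-step update.
#'
#' Sign convention: if `g_sub` equals `g_full` translated by +d (i.e.
#' `g_sub(x) = g_full(x - d)`), the updated field moves by +d.
#'
#' @param g_full,g_sub volumes (arrays or [volume3d()]) on the same grid,
#'   already at the estimation binning.
#' @param dvf_i numeric `(nx, ny, nz, 3)` array: current block displacement
#'   field in units of the working grid's voxels.
#' @param cfg an [flow_config()]; the effective kernel is
#'   `kernel_sigma / binning` working voxels.
#' @return Updated `(nx, ny, nz, 3)` array.
#' @export
optical_flow_update <- function(g_full, g_sub, dvf_i = NULL,
                                cfg = flow_config()) {
  A <- as_vol_array(g_full)
  B <- as_vol_array(g_sub)
  if (!identical(dim(A), dim(B))) stop("volumes must share one grid")
  if (is.null(dvf_i)) dvf_i <- array(0, c(dim(A), 3))
  if (!identical(dim(dvf_i)[1:3], dim(A)))
    stop("dvf_i must live on the volumes' grid")
  # delta relates the volumes by g_sub(x) = g_full(x + delta(x)); the
  # block field uses the opposite orientation
  -flow_residual_estimate(A, B, cfg, init = -dvf_i)
}

# Incremental node update used by the joint loop.  The flow measurements
# are residual displacements of each sub-tomogram relative to the full
# reconstruction; since g^F carries the mean of the uncompensated residual,
# each update is modelled as S_i Delta - mean_j(S_j Delta) and the node
# increments solve the centred system.  The second-difference penalty acts
# on the increments only, so the accumulated field is not biased against
# genuine temporal curvature (the amplitude law is saturating, not linear).
# The centring leaves one unobservable direction (block averages constant
# across sub-tomograms); the flow never constrains it, and accumulated
# noise would random-walk along it.  With `resolve_null = TRUE` the
# accumulated field's coefficient along that direction is set to the value
# minimizing the total temporal curvature given the observable components —
# the loop applies this once after its final iteration, so the curvature
# prior is imposed exactly once and the iteration dynamics stay untouched.
# With a single sub-tomogram the centring is skipped (the mean is the
# block itself).
deconvolve_increment <- function(dvf, updates, reg_weight = 0.1,
                                 resolve_null = FALSE) {
  N <- length(updates)
  m <- dim(updates[[1]])
  S <- matrix(0, N, N + 1)
  for (i in seq_len(N)) S[i, c(i, i + 1)] <- 0.5
  Sr <- S[, -1, drop = FALSE]
  if (N > 1) Sr <- Sr - matrix(colMeans(Sr), N, N, byrow = TRUE)
  DtD <- 0
  if (N >= 2) {
    D <- matrix(0, N - 1, N + 1)
    for (k in seq_len(N - 1)) D[k, k:(k + 2)] <- c(1, -2, 1)
    D <- D[, -1, drop = FALSE]
    DtD <- crossprod(D)
  }
  # the second-difference penalty renders the centred solve well posed
  # (the nullspace direction has nonzero temporal curvature)
  M <- crossprod(Sr) + reg_weight * DtD
  U <- vapply(updates, as.numeric, numeric(prod(m)))          # V x N
  Ncur <- vapply(dvf$nodes[-1], as.numeric, numeric(prod(m))) # V x N
  nn <- Ncur + (U %*% Sr) %*% solve(M)
  if (resolve_null && N > 1 && is.matrix(DtD)) {
    sv <- svd(Sr)
    if (sv$d[N] < 1e-8 * sv$d[1]) {
      # curvature-minimizing coefficient of the unobservable direction
      ns <- sv$v[, N]
      Dv <- D %*% ns
      den <- sum(Dv^2)
      if (den > 0) {
        beta <- -(nn %*% t(D) %*% Dv) / den
        nn <- nn + beta %*% t(ns)
      }
    }
  }
  nodes <- c(list(array(0, m)),
             lapply(seq_len(N), function(k) array(nn[, k], m)))
  dvf4d(dvf$node_times, nodes, dvf$spatial_step, dvf$grid_shape)
}

#' Deconvolve block DVFs onto time nodes
#'
#' Each sub-tomogram's optical-flow estimate is a time average of the true
#' deformation over that block, which underestimates a growing deformation
#' and leaves discontinuities between blocks.  This solves, independently
#' per voxel and axis, the Tikhonov-regularized least squares for the
#' `N + 1` node values of the piecewise-linear DVF: the averaging matrix S
#' maps node values to per-block means (midpoint rule for uniformly spread
#' acquisition, `(node_i + node_{i+1}) / 2`, or exact time averages of the
#' linear interpolant over the block's acquisition times), the penalty is
#' the squared second difference across nodes, and the t = 0 node is fixed
#' at zero.
#'
#' @param block_dvfs list of `(mx, my, mz, 3)` arrays, one per sub-tomogram,
#'   in acquisition order.
#' @param scheme an [acquisition_scheme()] (needed only for
#'   `method = "exact"`).
#' @param reg_weight Tikhonov weight of the temporal second-difference
#'   penalty.
#' @param spatial_step,grid_shape stored in the returned [dvf4d()].
#' @param method `"midpoint"` (default) or `"exact"` block averaging.
#' @return An [dvf4d()] with `length(block_dvfs) + 1` equally spaced nodes.
#' @export
temporal_deconvolve <- function(block_dvfs, scheme = NULL, reg_weight = 0.1,
                                spatial_step = 1L, grid_shape = NULL,
                                method = c("midpoint", "exact")) {
  method <- match.arg(method)
  N <- length(block_dvfs)
  if (N < 1) stop("at least one sub-tomogram block is required")
  m <- dim(block_dvfs[[1]])
  node_times <- seq(0, 1, length.out = N + 1)
  # S over nodes 0..N (columns), one row per block
  S <- matrix(0, N, N + 1)
  if (method == "midpoint" || is.null(scheme)) {
    for (i in seq_len(N)) S[i, c(i, i + 1)] <- 0.5
  } else {
    for (i in seq_len(N)) {
      tt <- scheme$time[scheme$subtomo == i]
      for (k in 0:N) {
        # hat basis of node k evaluated at the block's acquisition times
        phi <- rep(0, length(tt))
        tk <- node_times[k + 1]
        if (k > 0) {
          lo <- node_times[k]
          w <- tt >= lo & tt <= tk
          phi[w] <- phi[w] + (tt[w] - lo) / (tk - lo)
        }
        if (k < N) {
          hi <- node_times[k + 2]
          w <- tt > tk & tt <= hi
          phi[w] <- phi[w] + (hi - tt[w]) / (hi - tk)
        }
        if (k == N) phi[tt >= tk] <- pmax(phi[tt >= tk], 1)
        S[i, k + 1] <- mean(phi)
      }
    }
  }
  # drop the fixed t = 0 node (value 0)
  Sr <- S[, -1, drop = FALSE]
  # second differences over all N + 1 nodes, with node 0 eliminated
  D <- NULL
  if (N >= 2) {
    D <- matrix(0, N - 1, N + 1)
    for (k in seq_len(N - 1)) D[k, k:(k + 2)] <- c(1, -2, 1)
    D <- D[, -1, drop = FALSE]
  }
  M <- crossprod(Sr) + if (is.null(D)) 0 else reg_weight * crossprod(D)
  b <- vapply(block_dvfs, as.numeric, numeric(prod(m)))  # (vox*3) x N
  sol <- t(solve(M, t(b %*% Sr)))                         # (vox*3) x N
  if (is.null(grid_shape)) grid_shape <- as.integer(m[1:3] * spatial_step)
  nodes <- c(list(array(0, m)),
             lapply(seq_len(N), function(k) array(sol[, k], m)))
  dvf4d(node_times, nodes, spatial_step, grid_shape)
}
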