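#' Time-evolving deformation vector field
#'
#' A DVF `Gamma(x, t)` is stored as displacement fields at a small set of
#' interpolation nodes in normalized time and linearly interpolated in
#' between.  For an acquisition with `N` sub-tomograms there are `N + 1`
#' nodes, one at the beginning / end of each sub-tomogram; the node at
#' `t = 0` is identically zero (the reference state is the undeformed
#' sample, which anchors the otherwise free global degrees of freedom).
#'
#' Displacements are pull-back vectors in voxels of the full-resolution
#' reconstruction grid: the sample at time t reads the reference volume at
#' `x + Gamma(x, t)`.  Node fields may live on a grid downsampled by an
#' integer factor `spatial_step`; they are interpolated trilinearly when
#' evaluated.
#'
#' @param node_times strictly increasing normalized times in `[0, 1]`,
#'   starting at 0.
#' @param nodes list of numeric 4-D arrays `(mx, my, mz, 3)`, one per node:
#'   the x, y, z displacement components on the (possibly downsampled) grid.
#' @param spatial_step integer downsampling factor of the node grids
#'   relative to the reconstruction grid.
#' @param grid_shape integer length-3 full-resolution volume shape.
#' @return An object of class `nct_dvf`.
#' @export
dvf4d <- function(node_times, nodes, spatial_step = 1L, grid_shape) {
  stopifnot(is.list(nodes), length(nodes) == length(node_times),
            length(node_times) >= 1, length(grid_shape) == 3)
  if (any(diff(node_times) <= 0)) stop("node_times must be strictly increasing")
  if (abs(node_times[1]) > 1e-12) stop("the first node must be at t = 0")
  if (any(node_times < 0 | node_times > 1)) stop("node_times must lie in [0, 1]")
  m <- dim(nodes[[1]])
  if (length(m) != 4 || m[4] != 3)
    stop("each node field must be an (mx, my, mz, 3) array")
  for (f in nodes) {
    if (!identical(dim(f), m)) stop("all node fields must share one grid")
    if (!all(is.finite(f))) stop("node fields contain non-finite values")
  }
  if (max(abs(nodes[[1]])) > 1e-12)
    stop("the t = 0 node field must be identically zero (Gamma(x, 0) = 0)")
  structure(list(node_times = as.numeric(node_times), nodes = nodes,
                 spatial_step = as.integer(spatial_step),
                 grid_shape = as.integer(grid_shape)),
            class = "nct_dvf")
}

#' @export
print.nct_dvf <- function(x, ...) {
  m <- dim(x$nodes[[1]])[1:3]
  mx <- max(vapply(x$nodes, function(f) max(abs(f)), 0))
  cat(sprintf("<nct_dvf> %d nodes at t = %s; grid %s (step %d of %s); max |disp| %.3g px\n",
              length(x$nodes), paste(signif(x$node_times, 3), collapse = ", "),
              paste(m, collapse = "x"), x$spatial_step,
              paste(x$grid_shape, collapse = "x"), mx))
  invisible(x)
}

#' Zero deformation field
#'
#' @param grid_shape full-resolution volume shape.
#' @param n_subtomo number of sub-tomograms; the field has `n_subtomo + 1`
#'   equally spaced nodes.
#' @param spatial_step integer downsampling of the node grids.
#' @return An all-zero [dvf4d()].
#' @export
dvf_zero <- function(grid_shape, n_subtomo = 1L, spatial_step = 1L) {
  m <- dvf_grid_dim(grid_shape, spatial_step)
  z <- array(0, c(m, 3))
  dvf4d(seq(0, 1, length.out = n_subtomo + 1),
        rep(list(z), n_subtomo + 1), spatial_step, grid_shape)
}

dvf_grid_dim <- function(grid_shape, spatial_step) {
  if (any(grid_shape %% spatial_step != 0))
    stop("spatial_step must divide the grid shape")
  as.integer(grid_shape %/% spatial_step)
}

# time interpolation weights: bracketing nodes (k, k+1) and weight on k+1
dvf_time_bracket <- function(dvf, t) {
  if (t < -1e-12 || t > 1 + 1e-12) stop("t must lie in [0, 1]")
  t <- min(max(t, 0), 1)
  nt <- dvf$node_times
  if (t <= nt[1]) return(list(k = 1L, k1 = 1L, w = 0))
  if (t >= nt[length(nt)]) return(list(k = length(nt), k1 = length(nt), w = 0))
  k <- findInterval(t, nt, rightmost.closed = TRUE)
  list(k = k, k1 = k + 1L, w = (t - nt[k]) / (nt[k + 1] - nt[k]))
}

# blended displacement field at time t, as an (mx, my, mz, 3) array in
# full-resolution voxel units
dvf_blend <- function(dvf, t) {
  br <- dvf_time_bracket(dvf, t)
  if (br$w == 0) dvf$nodes[[br$k]]
  else (1 - br$w) * dvf$nodes[[br$k]] + br$w * dvf$nodes[[br$k1]]
}

#' Evaluate a DVF at points
#'
#' Returns `Gamma(x, t)` by linear interpolation between the two bracketing
#' node fields, each sampled trilinearly in space; queries outside the grid
#' return zero displacement (the sample is surrounded by empty space).
#'
#' @param dvf an [dvf4d()] object.
#' @param points numeric `n x 3` matrix of world coordinates in
#'   full-resolution voxel units (origin at the volume centre).
#' @param t normalized time in `[0, 1]`.
#' @return Numeric `n x 3` matrix of displacement vectors (voxels).
#' @export
dvf_evaluate <- function(dvf, points, t) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0) return(matrix(0, 0, 3))
  disp <- dvf_blend(dvf, t)
  cpp_disp_at_points(as.numeric(disp), dim(disp)[1:3], dvf$spatial_step, points)
}

#' Inverse DVF displacements
#'
#' Returns displacements `v = Gamma^{-1}(x, t)` such that
#' `x + v + Gamma(x + v, t)` is approximately `x`.  `mode = "negate"` uses the
#' first-order approximation `-Gamma(x, t)`; `mode = "fixed_point"` refines it
#' by the iteration `v <- -Gamma(x + v, t)`, which is exact for rigid fields
#' and substantially more accurate for smooth ones.
#'
#' @inheritParams dvf_evaluate
#' @param mode `"fixed_point"` (default) or `"negate"`.
#' @param n_iter number of fixed-point iterations (>= 1).
#' @return Numeric `n x 3` matrix of inverse displacements.  If the
#'   composition residual grows between iterations a warning is raised and
#'   the last iterate is returned.
#' @export
dvf_invert <- function(dvf, points, t, mode = c("fixed_point", "negate"),
                       n_iter = 5L) {
  mode <- match.arg(mode)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0) return(matrix(0, 0, 3))
  disp <- dvf_blend(dvf, t)
  if (mode == "negate")
    return(-cpp_disp_at_points(as.numeric(disp), dim(disp)[1:3],
                               dvf$spatial_step, points))
  stopifnot(n_iter >= 1)
  out <- cpp_invert_points(as.numeric(disp), dim(disp)[1:3], dvf$spatial_step,
                           points, as.integer(n_iter))
  r <- out$residual
  if (length(r) >= 2 && r[length(r)] > r[1] + 1e-12)
    warning("fixed-point DVF inversion did not converge; returning last iterate")
  out$disp
}

#' Warp a volume through a DVF
#'
#' Pull-back warp: `out(x) = vol(x + Gamma(x, t))` with trilinear
#' interpolation and zero fill outside the grid.  `direction = "inverse"`
#' uses the fixed-point inverse field instead, so that forward and inverse
#' warps approximately undo each other.
#'
#' @param vol an [volume3d()] or 3-D array.
#' @param dvf an [dvf4d()] whose `grid_shape` matches the volume.
#' @param t normalized time in `[0, 1]`.
#' @param direction `"forward"` (pull-back by `Gamma`) or `"inverse"`.
#' @param n_iter fixed-point iterations for the inverse.
#' @return A warped object of the same type as `vol`.
#' @export
warp_volume <- function(vol, dvf, t, direction = c("forward", "inverse"),
                        n_iter = 5L) {
  direction <- match.arg(direction)
  a <- as_vol_array(vol)
  if (!identical(as.integer(dim(a)), dvf$grid_shape))
    stop("volume shape does not match the DVF grid_shape")
  disp <- dvf_blend(dvf, t)
  m <- dim(disp)[1:3]
  if (direction == "inverse")
    disp <- cpp_invert_grid(as.numeric(disp), m, dvf$spatial_step,
                            as.integer(n_iter))$field
  w <- cpp_warp(as.numeric(a), dim(a), as.numeric(disp), m, dvf$spatial_step)
  out <- array(w, dim(a))
  if (inherits(vol, "nct_volume")) volume3d(out, vol$voxel_size) else out
}

#' Upscale a downsampled DVF to the full-resolution grid
#'
#' Trilinearly interpolates each node field onto the full grid;
#' displacement values are unchanged (they are stored in full-resolution
#' voxel units throughout).
#'
#' @param dvf an [dvf4d()].
#' @param factor upsampling factor; must equal the DVF's `spatial_step`.
#' @return A [dvf4d()] with `spatial_step = 1`.
#' @export
upscale_dvf <- function(dvf, factor = dvf$spatial_step) {
  if (factor != dvf$spatial_step)
    stop("factor must equal the DVF's spatial_step")
  if (factor == 1) return(dvf)
  gs <- dvf$grid_shape
  nodes <- lapply(dvf$nodes, function(f) {
    array(cpp_upscale_disp(as.numeric(f), dim(f)[1:3], dvf$spatial_step, gs),
          c(gs, 3))
  })
  # enforce the boundary condition exactly against round-off
  nodes[[1]][] <- 0
  dvf4d(dvf$node_times, nodes, 1L, gs)
}

# maximum displacement magnitude over all nodes (used for ray clipping)
dvf_max_disp <- function(dvf) {
  max(vapply(dvf$nodes, function(f) max(abs(f)), 0))
}
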