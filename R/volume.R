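#' Scalar 3-D volume
#'
#' Light container for a scalar reconstruction / phantom grid.  Most functions
#' in the package accept either an `nct_volume` or a bare numeric 3-D array.
#'
#' @param data numeric 3-D array, indexed (x, y, z).
#' @param voxel_size scalar physical voxel size (1 = work in voxel units).
#' @return An object of class `nct_volume`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)))
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size = 1) {
  data <- unclass(data)
  stopifnot(is.numeric(data), length(dim(data)) == 3, all(dim(data) > 0))
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size), class = "nct_volume")
}

#' @export
print.nct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nct_volume> %d x %d x %d voxels (voxel size %g), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

# accept nct_volume or bare array
as_vol_array <- function(vol) {
  if (inherits(vol, "nct_volume")) vol$data
  else if (is.array(vol) && length(dim(vol)) == 3) vol
  else stop("expected an nct_volume or a 3-D array")
}

#' Stack of 2-D projections with acquisition metadata
#'
#' @param images numeric 3-D array `(nu, nv, n)`: detector u (horizontal,
#'   perpendicular to the rotation axis) by v (vertical, parallel to the
#'   rotation axis) by projection.
#' @param angles rotation angles in radians, one per projection.
#' @param times normalized acquisition times in `[0, 1]`, nondecreasing in
#'   acquisition order.
#' @param subtomo integer sub-tomogram index (1-based) per projection.
#' @param shifts numeric `n x 2` matrix of per-projection detector shifts
#'   (du, dv) in pixels; the measured image is the ideal projection translated
#'   by its shift.
#' @return An object of class `nct_projections`.
#' @export
projection_stack <- function(images, angles, times = NULL, subtomo = NULL,
                             shifts = NULL) {
  stopifnot(is.numeric(images), length(dim(images)) == 3)
  n <- dim(images)[3]
  if (n == 0) stop("empty projection stack")
  if (length(angles) != n) stop("length(angles) must match the number of images")
  if (is.null(times)) times <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  if (is.null(subtomo)) subtomo <- rep(1L, n)
  if (is.null(shifts)) shifts <- matrix(0, n, 2)
  shifts <- matrix(as.numeric(shifts), ncol = 2)
  if (length(times) != n || length(subtomo) != n || nrow(shifts) != n)
    stop("angles, times, subtomo and shifts must all have one entry per image")
  if (any(times < 0 | times > 1)) stop("times must lie in [0, 1]")
  if (is.unsorted(times)) stop("times must be nondecreasing in acquisition order")
  if (diff(range(angles)) > pi + 1e-9)
    stop("angles must span at most one half turn")
  structure(list(images = unclass(images), angles = as.numeric(angles),
                 times = as.numeric(times), subtomo = as.integer(subtomo),
                 shifts = shifts),
            class = "nct_projections")
}

#' @export
print.nct_projections <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<nct_projections> %d projections, %d x %d detector, %d sub-tomogram(s)\n",
              d[3], d[1], d[2], length(unique(x$subtomo))))
  invisible(x)
}

# subset a stack by projection index, keeping metadata aligned
subset_stack <- function(stack, idx) {
  projection_stack(stack$images[, , idx, drop = FALSE], stack$angles[idx],
                   stack$times[idx], stack$subtomo[idx],
                   stack$shifts[idx, , drop = FALSE])
}

#' Interleaved angular acquisition schedule
#'
#' Maps the acquisition index of each projection to its rotation angle,
#' normalized time and sub-tomogram.  The full half-turn scan of `n_angles`
#' equidistant angles is split into `n_subtomo` temporally contiguous
#' sub-tomograms; sub-tomogram i contains every `n_subtomo`-th angle
#' (0-based angle indices i-1, i-1+n_subtomo, ...), so each sub-tomogram
#' spans the whole angular range at a coarser angular step.
#'
#' @param n_angles total number of projections.
#' @param n_subtomo number of interleaved sub-tomograms; must divide
#'   `n_angles`.
#' @param angle_span angular range in radians (half turn by default); angles
#'   are `k * angle_span / n_angles`, k = 0 .. n_angles - 1.
#' @return A data.frame with columns `index` (acquisition order, 1-based),
#'   `angle` (radians), `time` (normalized to `[0, 1]`) and `subtomo`
#'   (1-based), with attributes `n_angles` and `n_subtomo`.
#' @examples
#' sch <- acquisition_scheme(8, 2)
#' split(round(sch$angle / pi * 8), sch$subtomo)
#' @export
acquisition_scheme <- function(n_angles, n_subtomo, angle_span = pi) {
  stopifnot(n_angles >= 1, n_subtomo >= 1)
  if (n_angles %% n_subtomo != 0)
    stop("n_subtomo must divide n_angles for a clean interleaving")
  per <- n_angles %/% n_subtomo
  j <- seq_len(n_angles) - 1L
  subtomo <- j %/% per + 1L
  within <- j %% per
  angle_idx <- (subtomo - 1L) + n_subtomo * within
  out <- data.frame(index = j + 1L,
                    angle = angle_idx * angle_span / n_angles,
                    time = if (n_angles == 1) 0 else j / (n_angles - 1),
                    subtomo = subtomo)
  attr(out, "n_angles") <- as.integer(n_angles)
  attr(out, "n_subtomo") <- as.integer(n_subtomo)
  class(out) <- c("nct_scheme", "data.frame")
  out
}
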