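# Reconstruction and DVF quality metrics: Fourier shell correlation with the
# 1/2-bit information threshold, DVF RMS error, DVF principal components and
# gray-level histogram bimodality.

tukey_window1d <- function(n, alpha = 0.2) {
  # cosine-tapered window: flat centre, alpha/2 taper at each edge
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

tukey_mask3 <- function(shape, alpha = 0.2) {
  wx <- tukey_window1d(shape[1], alpha)
  wy <- tukey_window1d(shape[2], alpha)
  wz <- tukey_window1d(shape[3], alpha)
  outer(outer(wx, wy), wz)
}

fftfreq <- function(n) {
  k <- c(0:(floor(n / 2)), seq.int(-(ceiling(n / 2) - 1), -1))
  k[seq_len(n)] / n
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the 3-D Fourier transforms,
#' `Re sum(Fa conj(Fb)) / sqrt(sum|Fa|^2 sum|Fb|^2)`, together with the
#' 1/2-bit information threshold
#' `T(r) = (0.2071 + 1.9102 / sqrt(n_eff)) / (1.2071 + 0.9102 / sqrt(n_eff))`
#' with `n_eff = n_voxels(r) / 2` (halved for Hermitian symmetry).  The
#' resolution is read off at the first threshold crossing, linearly
#' interpolated in frequency.  A raised-cosine (Tukey) real-space mask with
#' 10% margins suppresses edge leakage before the transform.
#'
#' @param vol_a,vol_b volumes ([volume3d()] or arrays) of equal shape.
#' @param shell_width shell width in cycles/pixel (default one Fourier
#'   pixel of the largest dimension).
#' @param mask apply the Tukey mask (default TRUE).
#' @param voxel_size physical voxel size used to express
#'   `resolution_length`.
#' @return A data.frame of class `nct_fsc` with columns `freq` (shell
#'   midpoints, cycles/pixel up to Nyquist), `correlation`, `n_voxels`
#'   and `threshold`, and attributes `resolution_freq` (cycles/pixel; NA if
#'   no crossing below Nyquist) and `resolution_length`.
#' @export
fsc <- function(vol_a, vol_b, shell_width = NULL, mask = TRUE,
                voxel_size = 1) {
  A <- as_vol_array(vol_a)
  B <- as_vol_array(vol_b)
  if (!identical(dim(A), dim(B))) stop("volumes must have equal shapes")
  if (all(A == 0) || all(B == 0))
    stop("FSC undefined for an all-zero volume")
  d <- dim(A)
  if (is.null(shell_width)) shell_width <- 1 / max(d)
  if (mask) {
    w <- tukey_mask3(d)
    A <- A * w
    B <- B * w
  }
  Fa <- fft(A)
  Fb <- fft(B)
  fr <- sqrt(outer(outer(fftfreq(d[1])^2, fftfreq(d[2])^2, `+`),
                   fftfreq(d[3])^2, `+`))
  keep <- fr <= 0.5
  shell <- floor(fr[keep] / shell_width) + 1L
  ns <- max(shell)
  num <- rowsum(Re(Fa[keep] * Conj(Fb[keep])), shell)
  da <- rowsum(abs(Fa[keep])^2, shell)
  db <- rowsum(abs(Fb[keep])^2, shell)
  nvox <- as.vector(rowsum(rep(1, sum(keep)), shell))
  corr <- as.vector(num) / sqrt(as.vector(da) * as.vector(db))
  corr[!is.finite(corr)] <- 0
  freq <- (seq_len(ns) - 0.5) * shell_width
  neff <- pmax(nvox / 2, 1)
  thr <- (0.2071 + 1.9102 / sqrt(neff)) / (1.2071 + 0.9102 / sqrt(neff))
  res_f <- fsc_crossing(freq, corr, thr)
  out <- data.frame(freq = freq, correlation = corr, n_voxels = nvox,
                    threshold = thr)
  attr(out, "resolution_freq") <- res_f
  attr(out, "resolution_length") <- if (is.na(res_f)) NA_real_
                                    else voxel_size / res_f
  class(out) <- c("nct_fsc", "data.frame")
  out
}

# first crossing of the correlation below the threshold curve, linearly
# interpolated between the bracketing shells
fsc_crossing <- function(freq, corr, thr) {
  diffc <- corr - thr
  below <- which(diffc < 0)
  if (length(below) == 0) return(NA_real_)
  k <- below[1]
  if (k == 1) return(freq[1])
  f0 <- freq[k - 1]; f1 <- freq[k]
  d0 <- diffc[k - 1]; d1 <- diffc[k]
  f0 + d0 / (d0 - d1) * (f1 - f0)
}

#' @export
print.nct_fsc <- function(x, ...) {
  rf <- attr(x, "resolution_freq")
  cat(sprintf("<nct_fsc> %d shells up to Nyquist; 1/2-bit resolution at %s cycles/px\n",
              nrow(x), if (is.na(rf)) "no crossing" else sprintf("%.4f", rf)))
  invisible(x)
}

#' Plot an FSC curve with its 1/2-bit threshold
#'
#' @param x an [fsc()] result.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics lines abline legend
#' @export
plot.nct_fsc <- function(x, ...) {
  plot(x$freq, x$correlation, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "spatial frequency (cycles/pixel)", ylab = "FSC", ...)
  lines(x$freq, x$threshold, lty = 2)
  rf <- attr(x, "resolution_freq")
  if (!is.na(rf)) abline(v = rf, col = "grey60", lty = 3)
  legend("topright", c("FSC", "1/2-bit threshold"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' RMS discrepancy between two DVFs
#'
#' Root mean square of the vector difference magnitude between two
#' deformation fields, over the voxels of a support mask and over a list of
#' time samples (default: the estimated field's node times).
#'
#' @param dvf_est,dvf_true [dvf4d()] objects on commensurate full-resolution
#'   grids (each is evaluated on the full grid before comparison).
#' @param mask logical array over the full grid (default: everywhere).
#' @param t_samples times at which the fields are compared.
#' @return RMS error in voxels.
#' @export
dvf_rms_error <- function(dvf_est, dvf_true, mask = NULL,
                          t_samples = dvf_est$node_times) {
  gs <- dvf_est$grid_shape
  if (!identical(gs, dvf_true$grid_shape))
    stop("fields must share grid_shape")
  if (is.null(mask)) mask <- array(TRUE, gs)
  if (!any(mask)) stop("empty support mask")
  e <- upscale_dvf(dvf_est)
  tr <- upscale_dvf(dvf_true)
  acc <- 0
  n <- 0
  for (t in t_samples) {
    de <- dvf_blend(e, t)
    dt <- dvf_blend(tr, t)
    dd <- de - dt
    m2 <- dd[, , , 1]^2 + dd[, , , 2]^2 + dd[, , , 3]^2
    acc <- acc + sum(m2[mask])
    n <- n + sum(mask)
  }
  sqrt(acc / n)
}

#' Principal components of a time-evolving DVF
#'
#' Stacks each node's 3-component displacement field as one observation and
#' computes an uncentred SVD (the t = 0 node anchors the natural origin, so
#' no mean removal).  The right singular vectors are spatial deformation
#' modes, the projections of the nodes onto them are the per-node weights
#' (the mode's time evolution), and the squared singular values give the
#' explained fraction of the total deformation.
#'
#' @param dvf an [dvf4d()].
#' @return A list: `components` (list of `(mx, my, mz, 3)` unit-norm mode
#'   arrays), `weights` (nodes x modes matrix), `explained_fraction`.
#' @export
dvf_pca <- function(dvf) {
  X <- t(vapply(dvf$nodes, as.numeric,
                numeric(length(dvf$nodes[[1]]))))  # nodes x (vox*3)
  G <- X %*% t(X)
  eig <- eigen(G, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-12
  nmod <- max(1L, sum(pos))
  lam <- pmax(eig$values[seq_len(nmod)], 0)
  U <- eig$vectors[, seq_len(nmod), drop = FALSE]
  sv <- sqrt(lam)
  comps <- lapply(seq_len(nmod), function(k) {
    v <- as.numeric(t(X) %*% U[, k])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    array(v, dim(dvf$nodes[[1]]))
  })
  weights <- U %*% diag(sv, nmod)
  tot <- sum(lam)
  list(components = comps, weights = weights,
       explained_fraction = if (tot > 0) lam / tot else rep(0, nmod))
}

#' Gray-level histograms and bimodality score
#'
#' Normalized histograms of one or more volumes inside a common mask, on a
#' shared value range, plus a valley-to-peak bimodality score: the two main
#' modes are located by 2-means on the (subsampled) masked voxel values, and
#' the score is the minimum histogram density between the modes divided by
#' the smaller of the two peak densities.  A perfectly binary volume scores
#' 0; blur fills the valley and raises the score.
#'
#' @param vols list of volumes ([volume3d()] or arrays) of equal shape.
#' @param mask logical array (default: everywhere).
#' @param n_bins number of histogram bins.
#' @return A list: `breaks`, `density` (one column per volume, each summing
#'   to 1), `bimodality` (score per volume), `modes` (2 x n matrix of mode
#'   locations).
#' @export
histogram_report <- function(vols, mask = NULL, n_bins = 100L) {
  if (inherits(vols, "nct_volume") || (is.array(vols) && length(dim(vols)) == 3))
    vols <- list(vols)
  arrs <- lapply(vols, as_vol_array)
  d <- dim(arrs[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  vals <- lapply(arrs, function(a) a[mask])
  rng <- range(unlist(lapply(vals, range)))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  dens <- vapply(vals, function(v) {
    h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                            1L), n_bins), n_bins)
    h / sum(h)
  }, numeric(n_bins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  modes <- matrix(0, 2, length(vals))
  bim <- vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    if (length(v) > 2e5) v <- v[seq(1, length(v), length.out = 2e5)]
    cq <- quantile(v, c(0.25, 0.75), names = FALSE)
    if (diff(cq) == 0) return(NA_real_)
    cen <- sort(kmeans(v, centers = cq, iter.max = 50)$centers[, 1])
    modes[, i] <<- cen
    b1 <- which.min(abs(mids - cen[1]))
    b2 <- which.min(abs(mids - cen[2]))
    if (b2 <= b1 + 1) return(NA_real_)
    # peaks near each mode, valley strictly between them
    p1 <- max(dens[max(1, b1 - 2):min(n_bins, b1 + 2), i])
    p2 <- max(dens[max(1, b2 - 2):min(n_bins, b2 + 2), i])
    valley <- min(dens[(b1 + 1):(b2 - 1), i])
    valley / min(p1, p2)
  }, numeric(1))
  list(breaks = breaks, mids = mids, density = dens, bimodality = bim,
       modes = modes)
}
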