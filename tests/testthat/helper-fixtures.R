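# Small programmatic fixtures shared across the test files.

# binary blob-free cylinder of radius R inside an (n, n, nz) grid
fixture_cylinder <- function(n = 64, nz = 32, R = 20) {
  v <- array(0, c(n, n, nz))
  x <- (seq_len(n) - 1) - (n - 1) / 2
  inside <- outer(x^2, x^2, `+`) <= R^2
  v[rep(inside, nz)] <- 1
  v
}

# smooth positive blob volume (separable Gaussian bump)
fixture_blob <- function(shape = c(32, 32, 16), sigma = shape[1] / 6) {
  g1 <- function(n, s) exp(-0.5 * (((seq_len(n) - 1) - (n - 1) / 2) / s)^2)
  outer(outer(g1(shape[1], sigma), g1(shape[2], sigma)),
        g1(shape[3], sigma / 2))
}

# smooth random displacement field with max vector magnitude `max_disp`
fixture_smooth_field <- function(shape, sigma = 10, max_disp = 2, seed = 2) {
  set.seed(seed)
  f <- array(0, c(shape, 3))
  for (c in 1:3)
    f[, , , c] <- gaussian_smooth3(array(rnorm(prod(shape)), shape), sigma)
  mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
  f * (max_disp / max(mag))
}

# two-node DVF (zero at t = 0, `field` at t = 1) on the field's own grid
fixture_dvf2 <- function(field, spatial_step = 1L,
                         grid_shape = dim(field)[1:3] * spatial_step) {
  dvf4d(c(0, 1), list(array(0, dim(field)), field),
        spatial_step, as.integer(grid_shape))
}
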