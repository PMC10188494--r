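# Separable truncated-Gaussian smoothing on matrices.
#
# The 2-D kernel is the outer product of a 1-D Gaussian truncated at radius
# 3*sigma and normalised to sum 1, so smoothing a constant field returns the
# constant away from edges. Near edges the kernel mass falling outside the
# map is handled by renormalisation: the smoothed field is divided by the
# smoothed indicator of "inside the map", i.e. weights are renormalised over
# the in-map kernel mass.

gauss_weights <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# n x n band matrix applying the 1-D kernel along one axis (zero padding)
gauss_band <- function(n, sigma) {
  w <- gauss_weights(sigma)
  r <- (length(w) - 1L) %/% 2L
  b <- matrix(0, n, n)
  for (k in -r:r) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    b[cbind(i[ok], j[ok])] <- w[k + r + 1L]
  }
  b
}

# Gaussian-smooth a matrix; renormalise = divide by smoothed ones (edge fix)
smooth_mat <- function(m, sigma, renormalise = TRUE) {
  if (sigma <= 0) stop("sigma must be > 0")
  br <- gauss_band(nrow(m), sigma)
  bc <- gauss_band(ncol(m), sigma)
  s <- br %*% m %*% t(bc)
  if (renormalise) {
    norm <- br %*% matrix(1, nrow(m), ncol(m)) %*% t(bc)
    s <- s / norm
  }
  s
}

# standardised smooth Gaussian random field (mean 0, sd 1)
random_field <- function(n_rows, n_cols, sigma) {
  z <- smooth_mat(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), sigma)
  (z - mean(z)) / stats::sd(as.vector(z))
}
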