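# shared fixtures and independent oracles

make_spec <- function(n = 40, f = 20, pixel_size = 10 / 3600) {
  grid_spec(origin_lon = 0, origin_lat = 0, pixel_size = pixel_size,
            n_rows = n, n_cols = n, coarse_factor = f)
}

# a raster filled with one class
uniform_lc <- function(class, spec = make_spec(), legend = default_legend()) {
  categorical_raster(matrix(legend[class], spec$n_rows, spec$n_cols),
                     spec, legend)
}

# brute-force per-pixel coarse aggregation (oracle for aggregate_to_coarse)
bf_aggregate <- function(lc, model) {
  spec <- lc$spec
  f <- spec$coarse_factor
  cd <- coarse_dims(spec)
  areas <- matrix(cell_areas(spec, model), spec$n_rows, spec$n_cols)
  out <- matrix(0, prod(cd), 7, dimnames = list(NULL, names(lc$legend)))
  for (i in seq_len(spec$n_rows)) for (j in seq_len(spec$n_cols)) {
    I <- (i - 1) %/% f + 1
    J <- (j - 1) %/% f + 1
    cell <- (I - 1) * cd[2] + J
    cname <- names(lc$legend)[match(lc$values[i, j], lc$legend)]
    out[cell, cname] <- out[cell, cname] + areas[i, j]
  }
  out
}

# brute-force circle-window habitat fraction (oracle for habitat_fraction)
bf_habitat_fraction <- function(lc, cfg) {
  spec <- lc$spec
  px_m <- landshift::pixel_size_m(spec, cfg$pixel_size_m)
  rpx <- cfg$radius / px_m
  hab <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (h in cfg$habitat_classes)
    hab <- hab | lc$values == lc$legend[h]
  crop <- lc$values == lc$legend["cropland"]
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  r <- floor(rpx)
  for (i in seq_len(spec$n_rows)) for (j in seq_len(spec$n_cols)) {
    if (!crop[i, j]) next
    nh <- 0L; nt <- 0L
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > rpx^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > spec$n_rows || jj < 1 || jj > spec$n_cols) next
      nt <- nt + 1L
      if (hab[ii, jj]) nh <- nh + 1L
    }
    out[i, j] <- nh / nt
  }
  out
}

# independent scalar evaluation of the truncated-Gaussian 2-D kernel at the
# origin (for the single-pixel adjacency example)
kernel_origin_value <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  w[r + 1]^2
}

# coarse state with a given cropland/natural split per cell
mk_state <- function(crop, other, spec) {
  area <- matrix(0, length(crop), 7,
                 dimnames = list(NULL, names(default_legend())))
  area[, "cropland"] <- crop
  area[, "forest"] <- other * 0.5
  area[, "grassland"] <- other * 0.3
  area[, "non_forest_vegetation"] <- other * 0.2
  coarse_state(area, spec)
}

# independent circle-offset enumeration (window membership oracle)
circle_offsets_for_test <- function(rpx) {
  r <- floor(rpx)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= rpx^2, , drop = FALSE]
}

# random categorical raster over all 7 classes
random_lc <- function(spec, seed, legend = default_legend()) {
  withr::with_seed(seed, {
    categorical_raster(matrix(sample(legend, spec$n_rows * spec$n_cols,
                                     replace = TRUE),
                              spec$n_rows, spec$n_cols), spec, legend)
  })
}
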