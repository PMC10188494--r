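const_raster <- function(v, spec, units = "") {
  continuous_raster(matrix(v, spec$n_rows, spec$n_cols), spec, units)
}

test_that("K: frozen regression value, positivity, organic-carbon monotonicity", {
  spec <- grid_spec(n_rows = 2, n_cols = 2, coarse_factor = 2)
  K <- k_from_soil(const_raster(30, spec), const_raster(40, spec),
                   const_raster(30, spec), const_raster(1.5, spec))
  expect_equal(K$values[1, 1], 0.0183515896, tolerance = 1e-8)
  # K > 0 across a texture grid; K non-increasing in organic carbon
  withr::with_seed(13, {
    for (k in 1:25) {
      g <- stats::rgamma(3, 1) + 0.05
      tx <- 100 * g / sum(g)
      ocs <- seq(0.1, 4, length.out = 8)
      kk <- sapply(ocs, function(oc)
        k_from_soil(const_raster(tx[1], spec), const_raster(tx[2], spec),
                    const_raster(tx[3], spec),
                    const_raster(oc, spec))$values[1, 1])
      expect_true(all(kk > 0))
      expect_true(all(diff(kk) <= 1e-12))
    }
  })
  expect_error(k_from_soil(const_raster(100, spec), const_raster(0, spec),
                           const_raster(0, spec), const_raster(1, spec)),
               "silt \\+ clay")
})

test_that("LS: flat-terrain closed form, inclined-plane hand evaluation, monotonicity", {
  spec <- make_spec(n = 12, f = 2)
  flat <- const_raster(100, spec, "m")
  ls <- ls_factor(flat, spec, pixel_size_m = 300)
  expect_equal(ls$ls$values, matrix(0.03, 12, 12), tolerance = 1e-9)
  # plane tilted along rows: interior pixel in (0-based) row r has upslope
  # area r*D^2 and exact Horn slope; evaluate the contributing-area formulas
  # by hand for comparison
  D <- 300
  s <- 0.05
  plane <- function(slope)
    continuous_raster(outer(12:1, rep(1, 12)) * slope * D, spec, "m")
  lsd <- ls_factor(plane(s), spec, pixel_size_m = D)
  r <- 5  # 0-based row index of fine row 6
  expect_equal(lsd$upslope_m2[6, 6], r * D^2)
  theta <- atan(s)
  beta <- (sin(theta) / 0.0896) / (3 * sin(theta)^0.8 + 0.56)
  m <- beta / (1 + beta)
  A <- r * D^2
  L <- ((A + D^2)^(m + 1) - A^(m + 1)) / (D^(m + 2) * 1^m * 22.13^m)
  S <- 10.8 * sin(theta) + 0.03
  expect_equal(lsd$ls$values[6, 6], L * S, tolerance = 1e-9)
  # steep-slope branch of S and monotonicity in slope at fixed position
  ls_at <- function(slope) ls_factor(plane(slope), spec,
                                     pixel_size_m = D)$ls$values[6, 6]
  expect_gt(ls_at(0.08), ls_at(0.04))
  # steep-slope branch (tan >= 0.09) by the same hand evaluation
  steep <- ls_factor(plane(0.2), spec, pixel_size_m = D)
  th2 <- atan(0.2)
  b2 <- (sin(th2) / 0.0896) / (3 * sin(th2)^0.8 + 0.56)
  m2 <- b2 / (1 + b2)
  L2 <- ((A + D^2)^(m2 + 1) - A^(m2 + 1)) / (D^(m2 + 2) * 22.13^m2)
  expect_equal(steep$ls$values[6, 6], L2 * (16.8 * sin(th2) - 0.5),
               tolerance = 1e-9)
  expect_true(all(abs(steep$tan_slope[2:11, 2:11] - 0.2) < 1e-9))
  # upslope cap bounds the contributing area
  capped <- ls_factor(plane(s), spec, upslope_cap = 2 * D^2,
                      pixel_size_m = D)
  expect_lte(max(capped$upslope_m2), 2 * D^2)
})

test_that("C factors: cropland area weighting and cover interpolation", {
  spec <- make_spec(n = 4, f = 2)
  leg <- default_legend()
  tab <- c_factor_defaults()
  # single crop group with C = 0.25 paints all cropland pixels
  lc <- uniform_lc("cropland", spec)
  sh1 <- matrix(1, 4, 1, dimnames = list(NULL, "crop_1"))
  tab1 <- tab; tab1$crops["crop_1"] <- 0.25
  expect_true(all(cropland_c(lc, sh1, tab1)$values == 0.25))
  # 50/50 shares with C 0.3 / 0.2 -> 0.25
  sh2 <- matrix(0.5, 4, 2, dimnames = list(NULL, c("crop_1", "crop_2")))
  tab2 <- tab; tab2$crops[c("crop_1", "crop_2")] <- c(0.3, 0.2)
  expect_true(all(cropland_c(lc, sh2, tab2)$values == 0.25))
  # Dirichlet shares equal the brute-force dot product, and stay convex
  withr::with_seed(3, {
    sh <- matrix(stats::rgamma(4 * 20, 0.5), 4, 20,
                 dimnames = list(NULL, names(tab$crops)))
    sh <- sh / rowSums(sh)
  })
  got <- cropland_c(lc, sh, tab)$values
  want <- as.vector(sh %*% tab$crops)
  ids <- cell_id_matrix(spec)
  expect_equal(got, matrix(want[ids], 4, 4))
  expect_true(all(got >= min(tab$crops) - 1e-12 &
                    got <= max(tab$crops) + 1e-12))
  # non-crop: endpoints and midpoint of the linear cover interpolation
  lcn <- uniform_lc("forest", spec)
  lcn$values[1, ] <- leg["grassland"]
  full <- const_raster(1, spec)
  none <- const_raster(0, spec)
  half <- const_raster(0.5, spec)
  cfull <- noncrop_c(lcn, full, full, tab)
  expect_equal(cfull$values[2, 1], tab$classes["forest", "C_full"])
  czero <- noncrop_c(lcn, none, none, tab)
  expect_equal(czero$values[1, 1], tab$classes["grassland", "C_bare"])
  chalf <- noncrop_c(lcn, half, half, tab)
  expect_equal(chalf$values[2, 2],
               mean(unlist(tab$classes["forest", c("C_bare", "C_full")])))
})

test_that("RUSLE product: zeros, arithmetic, linearity in each factor", {
  spec <- make_spec(n = 4, f = 2)
  R <- const_raster(100, spec); K <- const_raster(0.03, spec)
  LS <- const_raster(1.2, spec); C <- const_raster(0.2, spec)
  A <- rusle_a(R, K, LS, C)
  expect_equal(A$values, matrix(100 * 0.03 * 1.2 * 0.2, 4, 4))
  expect_true(all(rusle_a(R, K, LS, const_raster(0, spec))$values == 0))
  R2 <- const_raster(200, spec)
  expect_equal(rusle_a(R2, K, LS, C)$values, 2 * A$values)
  withr::with_seed(7, {
    Rr <- continuous_raster(matrix(stats::runif(16, 0, 5000), 4, 4), spec)
    lambda <- 3.7
    Rl <- continuous_raster(lambda * Rr$values, spec)
    expect_equal(rusle_a(Rl, K, LS, C)$values,
                 lambda * rusle_a(Rr, K, LS, C)$values)
  })
})

test_that("soil-loss aggregation: unit conversion, zero map, brute force, additivity", {
  # uniform A = 1 Mg/ha/yr over 1e9 ha -> exactly 1 Pg/yr
  spec <- grid_spec(n_rows = 10, n_cols = 10, coarse_factor = 10,
                    pixel_size = 1)
  model <- cell_area_model(uniform_area = 1e7)  # 100 pixels x 1e7 ha
  lc <- uniform_lc("cropland", spec)
  A1 <- continuous_raster(matrix(1, 10, 10), spec, "Mg ha-1 yr-1")
  agg <- aggregate_soil_loss(A1, lc, region_id = rep(1L, 1), model)
  expect_equal(agg$global[["all"]], 1)
  expect_equal(agg$global[["cropland"]], 1)
  A0 <- continuous_raster(matrix(0, 10, 10), spec, "")
  expect_true(all(aggregate_soil_loss(A0, lc, 1L, model)$totals$soil_loss_Pg == 0))
  # random raster against per-pixel summation; regions partition the total
  spec2 <- make_spec(n = 40, f = 20)
  model2 <- cell_area_model(uniform_area = 9)
  rl <- random_lc(spec2, seed = 9)
  withr::with_seed(10, {
    Ar <- continuous_raster(matrix(stats::rexp(1600, 1 / 5), 40, 40), spec2)
  })
  regions <- c(1L, 1L, 2L, 2L)
  agg2 <- aggregate_soil_loss(Ar, rl, regions, model2)
  expect_equal(agg2$global[["all"]], sum(Ar$values * 9) / 1e9)
  crop <- rl$values == default_legend()["cropland"]
  expect_equal(agg2$global[["cropland"]], sum(Ar$values[crop] * 9) / 1e9)
  tot <- agg2$totals
  expect_equal(sum(tot$soil_loss_Pg[tot$scope == "all"]),
               agg2$global[["all"]])
  # erosion classes respect the breakpoints
  cls <- aggregate_soil_loss(Ar, rl, regions, model2)$classes
  expect_true(all(cls[Ar$values < 0.5] == 1))
  expect_true(all(cls[Ar$values >= 20] == 7))
  expect_error(aggregate_soil_loss(Ar, rl, regions, model2,
                                   class_breaks = c(1, 2)), "six increasing")
})
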