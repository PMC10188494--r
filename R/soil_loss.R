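#' Soil erodibility K from soil properties
#'
#' EPIC-type algebraic approximation from texture and organic carbon:
#' \deqn{K = f_{csand} \, f_{cl-si} \, f_{orgC} \, f_{hisand} \times 0.1317}
#' with
#' `f_csand = 0.2 + 0.3 exp(-0.256 sand (1 - silt/100))`,
#' `f_cl-si = (silt / (clay + silt))^0.3`,
#' `f_orgC = 1 - 0.25 orgC / (orgC + exp(3.72 - 2.95 orgC))`,
#' `f_hisand = 1 - 0.7 s1 / (s1 + exp(-5.51 + 22.9 s1))`, `s1 = 1 - sand/100`.
#' The 0.1317 factor converts to SI units
#' (t ha h ha^-1 MJ^-1 mm^-1).
#'
#' @param sand,silt,clay texture [continuous_raster()]s in percent (summing
#'   to ~100).
#' @param orgC organic carbon [continuous_raster()] in percent.
#' @return K [continuous_raster()].
#' @export
k_from_soil <- function(sand, silt, clay, orgC) {
  sa <- sand$values; si <- silt$values; cl <- clay$values; oc <- orgC$values
  if (any(si + cl <= 0, na.rm = TRUE))
    stop("silt + clay must be > 0 (f_cl-si undefined)")
  if (any(oc < 0, na.rm = TRUE)) stop("orgC must be >= 0")
  f_csand <- 0.2 + 0.3 * exp(-0.256 * sa * (1 - si / 100))
  f_clsi <- (si / (cl + si))^0.3
  f_orgc <- 1 - 0.25 * oc / (oc + exp(3.72 - 2.95 * oc))
  s1 <- 1 - sa / 100
  f_hisand <- 1 - 0.7 * s1 / (s1 + exp(-5.51 + 22.9 * s1))
  continuous_raster(f_csand * f_clsi * f_orgc * f_hisand * 0.1317,
                    sand$spec, "t ha h ha-1 MJ-1 mm-1")
}

# Horn slope and aspect from a DEM; returns list(tan_slope, aspect_factor)
horn_slope <- function(z, D) {
  pad <- function(di, dj) {
    s <- shift_mat(z, di, dj)
    s[is.na(s)] <- z[is.na(s)]  # replicate edge
    s
  }
  gx <- ((pad(-1, 1) + 2 * pad(0, 1) + pad(1, 1)) -
           (pad(-1, -1) + 2 * pad(0, -1) + pad(1, -1))) / (8 * D)
  gy <- ((pad(-1, -1) + 2 * pad(-1, 0) + pad(-1, 1)) -
           (pad(1, -1) + 2 * pad(1, 0) + pad(1, 1))) / (8 * D)
  tan_s <- sqrt(gx^2 + gy^2)
  aspect <- atan2(gy, gx)
  x <- abs(sin(aspect)) + abs(cos(aspect))
  x[tan_s == 0] <- 1
  list(tan_slope = tan_s, aspect_factor = x)
}

# deterministic D8 flow accumulation; returns inflow area (m^2) per pixel
d8_accumulation <- function(z, D) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  dist <- sqrt(offs[, 1]^2 + offs[, 2]^2) * D
  # receiver of each pixel: steepest descent, ties by listed neighbour order
  recv <- integer(n)
  zvec <- as.vector(z)  # column-major
  idx <- function(i, j) (j - 1L) * nr + i
  best_drop <- rep(0, n)
  recv[] <- 0L
  for (k in 1:8) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    i <- rep(seq_len(nr), nc); j <- rep(seq_len(nc), each = nr)
    ni <- i + di; nj <- j + dj
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    drop <- rep(-Inf, n)
    drop[ok] <- (zvec[ok] - zvec[idx(ni[ok], nj[ok])]) / dist[k]
    better <- drop > best_drop + 1e-12
    best_drop[better] <- drop[better]
    recv[better] <- idx(ni[better], nj[better])
  }
  acc <- rep(0, n)  # inflow area entering each pixel, m^2
  ord <- order(zvec, decreasing = TRUE)
  cellA <- D^2
  for (p in ord) {
    r <- recv[p]
    if (r > 0L) acc[r] <- acc[r] + acc[p] + cellA
  }
  matrix(acc, nr, nc)
}

#' Slope length-steepness factor (two-dimensional approach)
#'
#' Computes LS per pixel from the DEM following the two-dimensional
#' contributing-area formulation: slope by 8-neighbour (Horn) finite
#' differences, upslope area by deterministic D8 flow accumulation (steepest
#' descent, ties to the first neighbour in scan order), then
#' \deqn{L = \frac{(A + D^2)^{m+1} - A^{m+1}}{D^{m+2} x^m 22.13^m}}
#' with `beta = (sin t / 0.0896) / (3 sin(t)^0.8 + 0.56)`,
#' `m = beta / (1 + beta)`, aspect factor `x = |sin a| + |cos a|`, and
#' `S = 10.8 sin t + 0.03` below 9\% slope (tan t < 0.09), else
#' `16.8 sin t - 0.5`. A flat DEM gives LS = 0.03 exactly.
#'
#' @param dem a [continuous_raster()] (m).
#' @param spec a [grid_spec()] (pixel metric).
#' @param upslope_cap cap on contributing area in m^2 (default 1 km^2),
#'   avoiding channelised-flow artefacts.
#' @param ls_cap cap on the LS value itself.
#' @param pixel_size_m optional explicit pixel size in metres.
#' @return list with `ls` ([continuous_raster()]) and diagnostic matrices
#'   `tan_slope`, `upslope_m2`, `m_exponent`.
#' @export
ls_factor <- function(dem, spec = dem$spec, upslope_cap = 1e6, ls_cap = Inf,
                      pixel_size_m = NULL) {
  D <- pixel_size_m(spec, pixel_size_m)
  if (D <= 0) stop("pixel size must be > 0")
  z <- dem$values
  hs <- horn_slope(z, D)
  sin_t <- sin(atan(hs$tan_slope))
  beta <- (sin_t / 0.0896) / (3 * sin_t^0.8 + 0.56)
  m <- beta / (1 + beta)
  A <- pmin(d8_accumulation(z, D), upslope_cap)
  x <- hs$aspect_factor
  L <- ((A + D^2)^(m + 1) - A^(m + 1)) / (D^(m + 2) * x^m * 22.13^m)
  S <- ifelse(hs$tan_slope < 0.09, 10.8 * sin_t + 0.03, 16.8 * sin_t - 0.5)
  ls <- pmin(L * S, ls_cap)
  list(ls = continuous_raster(ls, spec, ""), tan_slope = hs$tan_slope,
       upslope_m2 = A, m_exponent = m)
}

#' Default cover-management (C) factor table
#'
#' Editable defaults: one C value per crop group and bare/full-cover
#' endpoints per non-crop class. The values are literature-representative
#' placeholders spanning the usual range (row crops high, dense perennial
#' cover low); they are a configuration surface, not reference data.
#'
#' @param n_crop_groups number of crop groups (default 20).
#' @return list with `crops` (named numeric) and `classes` (data.frame with
#'   `C_bare`, `C_full` rows per class; water fixed at 0).
#' @export
c_factor_defaults <- function(n_crop_groups = 20L) {
  crops <- round(seq(0.45, 0.10, length.out = n_crop_groups), 3)
  names(crops) <- paste0("crop_", seq_len(n_crop_groups))
  classes <- data.frame(
    C_bare = c(forest = 0.30, grassland = 0.30, non_forest_vegetation = 0.35,
               urban = 0.005, barren = 0.40, water = 0),
    C_full = c(forest = 0.001, grassland = 0.01, non_forest_vegetation = 0.02,
               urban = 0.005, barren = 0.40, water = 0))
  list(crops = crops, classes = classes)
}

#' Cropland C factor from crop-group composition
#'
#' Area-weighted mean C over the crop groups of each coarse cell,
#' disaggregated uniformly to that cell's cropland pixels.
#'
#' @param lc a [categorical_raster()].
#' @param crop_shares matrix `n_cells x n_groups` of shares summing to 1 per
#'   cell (column names matching the C table).
#' @param table a [c_factor_defaults()]-style list.
#' @return a [continuous_raster()]: C on cropland pixels, NA elsewhere.
#' @export
cropland_c <- function(lc, crop_shares, table = c_factor_defaults()) {
  if (!all(colnames(crop_shares) %in% names(table$crops)))
    stop("crop share columns not all present in C table")
  if (any(abs(rowSums(crop_shares) - 1) > 1e-6))
    stop("crop shares must sum to 1 per cell")
  cvals <- table$crops[colnames(crop_shares)]
  c_cell <- as.vector(crop_shares %*% cvals)
  ids <- cell_id_matrix(lc$spec)
  cmat <- matrix(c_cell[ids], nrow(ids), ncol(ids))
  cmat[lc$values != class_id(lc$legend, "cropland")] <- NA
  continuous_raster(cmat, lc$spec, "")
}

#' Non-cropland C factor from fractional cover
#'
#' Linear interpolation between bare and full-cover endpoints:
#' `C = C_bare (1 - f) + C_full f`, with `f` = tree cover on forest pixels
#' and annual vegetation cover on grassland / non-forest vegetation pixels;
#' urban, barren and water take their configured constants.
#'
#' @param lc a [categorical_raster()].
#' @param tree_cover,fcover fraction [continuous_raster()]s in \[0, 1\].
#' @param table a [c_factor_defaults()]-style list.
#' @return a [continuous_raster()]: C on non-cropland pixels, NA on
#'   cropland.
#' @export
noncrop_c <- function(lc, tree_cover, fcover, table = c_factor_defaults()) {
  tc <- tree_cover$values; fc <- fcover$values
  if (any(tc < 0 | tc > 1 | fc < 0 | fc > 1, na.rm = TRUE))
    stop("cover fractions must be in [0, 1]")
  cl <- table$classes
  need <- setdiff(names(default_legend()), c("cropland"))
  if (!all(need %in% rownames(cl))) stop("missing class constants in C table")
  out <- matrix(NA_real_, nrow(tc), ncol(tc))
  leg <- lc$legend
  mix <- function(class, f) {
    sel <- lc$values == class_id(leg, class)
    out[sel] <<- cl[class, "C_bare"] * (1 - f[sel]) + cl[class, "C_full"] * f[sel]
  }
  mix("forest", tc)
  mix("grassland", fc)
  mix("non_forest_vegetation", fc)
  for (k in c("urban", "barren", "water"))
    out[lc$values == class_id(leg, k)] <- cl[k, "C_full"]
  continuous_raster(out, lc$spec, "")
}

#' Combined C factor over the whole map
#' @inheritParams cropland_c
#' @inheritParams noncrop_c
#' @return a [continuous_raster()] defined on every pixel.
#' @export
c_factor <- function(lc, crop_shares, tree_cover, fcover,
                     table = c_factor_defaults()) {
  cc <- cropland_c(lc, crop_shares, table)$values
  nc <- noncrop_c(lc, tree_cover, fcover, table)$values
  continuous_raster(ifelse(is.na(cc), nc, cc), lc$spec, "")
}

#' Annual soil loss A = R * K * LS * C
#'
#' The RUSLE product with the support-practice factor held at 1 (management
#' practices constant across scenarios).
#'
#' @param R,K,LS,C co-registered factor [continuous_raster()]s.
#' @return a [continuous_raster()] in Mg ha^-1 yr^-1.
#' @export
rusle_a <- function(R, K, LS, C) {
  if (!same_grid(R, K) || !same_grid(R, LS) || !same_grid(R, C))
    stop("factor grids differ")
  continuous_raster(R$values * K$values * LS$values * C$values,
                    R$spec, "Mg ha-1 yr-1")
}

#' Erosion classes and regional soil-loss totals
#'
#' Classifies per-pixel soil loss into seven classes by configurable
#' breakpoints and aggregates totals (Pg yr^-1, 1 Pg = 1e9 Mg) per region
#' for three scopes: all land, cropland, and historic cropland.
#'
#' @param A soil-loss [continuous_raster()] (Mg ha^-1 yr^-1).
#' @param lc a [categorical_raster()].
#' @param region_id integer vector over coarse cells (row-major).
#' @param model a [cell_area_model()].
#' @param class_breaks six increasing breakpoints bounding seven classes
#'   (defaults 0.5, 1, 2, 5, 10, 20 Mg ha^-1 yr^-1).
#' @param historic logical matrix of baseline cropland (or `NULL`).
#' @return list with `classes` (integer matrix 1..7), `totals` (data.frame
#'   region/scope/soil_loss_Pg) and `global` (named totals).
#' @export
aggregate_soil_loss <- function(A, lc, region_id, model = cell_area_model(),
                                class_breaks = c(0.5, 1, 2, 5, 10, 20),
                                historic = NULL) {
  if (!same_grid(A, lc)) stop("grids differ")
  if (length(class_breaks) != 6L || any(diff(class_breaks) <= 0))
    stop("class_breaks must be six increasing values")
  aremat <- pixel_area_matrix(A$spec, model)
  mass <- A$values * aremat  # Mg per pixel per yr
  cls <- matrix(findInterval(A$values, class_breaks) + 1L,
                nrow(A$values), ncol(A$values))
  ids <- cell_id_matrix(A$spec)
  reg <- matrix(region_id[ids], nrow(ids), ncol(ids))
  if (length(unique(region_id)) == 0L) stop("no regions")
  crop <- lc$values == class_id(lc$legend, "cropland")
  scopes <- list(all = matrix(TRUE, nrow(mass), ncol(mass)), cropland = crop)
  if (!is.null(historic)) scopes$historic_cropland <- crop & historic
  rows <- list()
  for (sc in names(scopes)) {
    keep <- scopes[[sc]] & !is.na(mass)
    tot <- tapply(mass[keep], factor(reg[keep], levels = sort(unique(region_id))),
                  sum)
    tot[is.na(tot)] <- 0
    rows[[sc]] <- data.frame(region = as.integer(names(tot)), scope = sc,
                             soil_loss_Pg = as.numeric(tot) / 1e9)
  }
  totals <- do.call(rbind, rows)
  rownames(totals) <- NULL
  global <- tapply(totals$soil_loss_Pg, totals$scope, sum)
  list(classes = cls, totals = totals, global = global)
}
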