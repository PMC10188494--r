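#' Pollination scoring configuration
#'
#' @param radius foraging radius in metres (default 2000, the flight range
#'   typical of wild pollinator communities).
#' @param threshold habitat sufficiency threshold as a fraction (default
#'   0.30: 30\% habitat in the window gives full sufficiency).
#' @param habitat_classes character vector of habitat class names (default
#'   forest, non-forest vegetation and grassland; drop `"grassland"` for the
#'   grassland-exclusion robustness variant).
#' @param class_bounds boundaries of the low/moderate/high score classes
#'   (defaults exact thirds; the printed 0.33/0.67 are rounded display).
#' @param pixel_size_m optional explicit pixel size in metres (otherwise
#'   derived from the grid spec via [pixel_size_m()]).
#' @return object of class `pollination_config`.
#' @export
pollination_config <- function(radius = 2000, threshold = 0.30,
                               habitat_classes = c("forest",
                                                   "non_forest_vegetation",
                                                   "grassland"),
                               class_bounds = c(1 / 3, 2 / 3),
                               pixel_size_m = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (radius <= 0) stop("radius must be > 0")
  structure(list(radius = radius, threshold = threshold,
                 habitat_classes = habitat_classes,
                 class_bounds = class_bounds, pixel_size_m = pixel_size_m),
            class = "pollination_config")
}

# integer offsets whose pixel-centre distance is within radius
circle_offsets <- function(radius_px) {
  r <- floor(radius_px)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off[off$di^2 + off$dj^2 <= radius_px^2, , drop = FALSE]
}

#' Habitat fraction around cropland pixels
#'
#' For every cropland pixel, the proportion of pixels within the foraging
#' radius (pixel centres within `radius` metres of the focal centre, uniform
#' planar metric) whose class is pollinator habitat. The denominator counts
#' all in-map window pixels, so water and urban count as non-habitat rather
#' than being excluded. Non-cropland pixels are nodata.
#'
#' @param lc a [categorical_raster()].
#' @param cfg a [pollination_config()].
#' @return a [continuous_raster()] of fractions in \[0, 1\].
#' @export
habitat_fraction <- function(lc, cfg = pollination_config()) {
  px_m <- pixel_size_m(lc$spec, cfg$pixel_size_m)
  radius_px <- cfg$radius / px_m
  if (radius_px < 0.5) stop("radius smaller than half a pixel: empty window")
  off <- circle_offsets(radius_px)
  hab <- matrix(0, lc$spec$n_rows, lc$spec$n_cols)
  for (h in cfg$habitat_classes)
    hab <- hab + (lc$values == class_id(lc$legend, h))
  hcount <- matrix(0, nrow(hab), ncol(hab))
  ncount <- matrix(0, nrow(hab), ncol(hab))
  ones <- matrix(1, nrow(hab), ncol(hab))
  for (k in seq_len(nrow(off))) {
    s <- shift_mat(hab, off$di[k], off$dj[k])
    w <- shift_mat(ones, off$di[k], off$dj[k])
    s[is.na(s)] <- 0; w[is.na(w)] <- 0
    hcount <- hcount + s
    ncount <- ncount + w
  }
  p <- hcount / ncount
  p[lc$values != class_id(lc$legend, "cropland")] <- NA
  continuous_raster(p, lc$spec, "fraction")
}

#' Sufficiency score from a habitat fraction
#'
#' Linear ramp saturating at the threshold: `s = min(p / threshold, 1)`, so
#' a window with at least 30\% habitat (default) scores 1 and lower habitat
#' shares score proportionally.
#'
#' @param p habitat fraction(s) in \[0, 1\] (NA passed through).
#' @param threshold sufficiency threshold (default 0.30).
#' @return score(s) in \[0, 1\].
#' @export
sufficiency_score <- function(p, threshold = 0.30) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  pmin(p / threshold, 1)
}

#' Score a land-cover map for pollination sufficiency
#'
#' Convenience wrapper: habitat fraction then sufficiency score.
#'
#' @inheritParams habitat_fraction
#' @return list with `p` and `s` [continuous_raster()]s (cropland pixels
#'   only).
#' @export
pollination_scores <- function(lc, cfg = pollination_config()) {
  p <- habitat_fraction(lc, cfg)
  s <- continuous_raster(sufficiency_score(p$values, cfg$threshold),
                         lc$spec, "score")
  list(p = p, s = s)
}

score_class <- function(s, bounds) {
  cut(s, breaks = c(-Inf, bounds, Inf), labels = c("low", "moderate", "high"),
      right = FALSE)  # left-closed; scores <= 1 so top class closed at 1
}

#' Summarise pollination sufficiency between two time points
#'
#' Bins scores into low / moderate / high classes (left-closed bounds at
#' exact thirds, top class closed at 1), sums class areas with the area
#' model at both times, restricts a second set of figures to historic
#' cropland (pixels that were cropland at t0), and tabulates the class
#' transition matrix over pixels scored at both times.
#'
#' @param s0,s1 score [continuous_raster()]s at the two time points (NA on
#'   non-cropland).
#' @param historic logical matrix: cropland mask at the baseline year.
#' @param model a [cell_area_model()].
#' @param cfg a [pollination_config()].
#' @return list with `areas` (data.frame class/time/scope/area_ha) and
#'   `transitions` (3 x 3 matrix of pixel counts, historic scope).
#' @export
summarize_pollination <- function(s0, s1, historic, model = cell_area_model(),
                                  cfg = pollination_config()) {
  if (!same_grid(s0, s1)) stop("grids differ")
  aremat <- pixel_area_matrix(s0$spec, model)
  lv <- c("low", "moderate", "high")
  one <- function(s, mask, time, scope) {
    keep <- !is.na(s$values) & mask
    cl <- score_class(s$values[keep], cfg$class_bounds)
    a <- tapply(aremat[keep], cl, sum)
    a[is.na(a)] <- 0
    data.frame(class = lv, time = time, scope = scope,
               area_ha = as.numeric(a[lv]))
  }
  all_mask <- matrix(TRUE, s0$spec$n_rows, s0$spec$n_cols)
  areas <- rbind(one(s0, all_mask, "t0", "all"),
                 one(s1, all_mask, "t1", "all"),
                 one(s0, historic, "t0", "historic"),
                 one(s1, historic, "t1", "historic"))
  areas$area_ha[is.na(areas$area_ha)] <- 0
  both <- !is.na(s0$values) & !is.na(s1$values) & historic
  trans <- table(factor(score_class(s0$values[both], cfg$class_bounds), lv),
                 factor(score_class(s1$values[both], cfg$class_bounds), lv))
  list(areas = areas, transitions = unclass(trans))
}
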