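#' Grid geometry for a two-level (coarse/fine) raster domain
#'
#' Defines the fine-pixel grid and the coarse-cell tiling used throughout the
#' package. Row 0 of the grid is the northernmost row; `origin_lat` is the
#' latitude of the grid's northern edge and `origin_lon` the longitude of its
#' western edge. Coarse cell (I, J) owns the block of fine rows
#' `[I * coarse_factor, (I + 1) * coarse_factor)` (0-based), and likewise for
#' columns.
#'
#' @param origin_lon western edge, decimal degrees.
#' @param origin_lat northern edge, decimal degrees.
#' @param pixel_size fine-pixel edge length in degrees (> 0).
#' @param n_rows,n_cols fine-grid dimensions; both must be divisible by
#'   `coarse_factor`.
#' @param coarse_factor fine pixels per coarse-cell side (>= 2).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon = 0, origin_lat = 0, pixel_size = 10 / 3600,
                      n_rows = 120L, n_cols = 120L, coarse_factor = 20L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  coarse_factor <- as.integer(coarse_factor)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (coarse_factor < 2L) stop("coarse_factor must be >= 2")
  if (n_rows %% coarse_factor != 0L || n_cols %% coarse_factor != 0L)
    stop("n_rows and n_cols must be divisible by coarse_factor")
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 pixel_size = pixel_size, n_rows = n_rows, n_cols = n_cols,
                 coarse_factor = coarse_factor),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d fine pixels of %.6f deg, coarse factor %d (%d x %d coarse cells)\n",
              x$n_rows, x$n_cols, x$pixel_size, x$coarse_factor,
              x$n_rows %/% x$coarse_factor, x$n_cols %/% x$coarse_factor))
  invisible(x)
}

#' Coarse-grid dimensions of a grid_spec
#' @param spec a [grid_spec()].
#' @return integer vector `c(nI, nJ)` of coarse rows and columns.
#' @export
coarse_dims <- function(spec) {
  c(spec$n_rows %/% spec$coarse_factor, spec$n_cols %/% spec$coarse_factor)
}

#' Planar pixel metric
#'
#' Metres per fine pixel under the uniform planar metric used for window
#' radii and slope lengths: the meridional arc of one pixel at the domain's
#' central latitude (one degree of arc = 111,320 m on the sphere used here).
#'
#' @param spec a [grid_spec()].
#' @param override if non-`NULL`, returned as-is (explicit metre size).
#' @return metres per pixel (scalar).
#' @export
pixel_size_m <- function(spec, override = NULL) {
  if (!is.null(override)) return(override)
  spec$pixel_size * 111320
}

# --- class legend ----------------------------------------------------------

.functional_types <- c("cropland", "grassland", "forest",
                       "non_forest_vegetation", "urban", "barren", "water")

#' Legend over the seven functional land-cover types
#'
#' The analysis runs on a 7-class functional legend: cropland, grassland,
#' forest, non-forest vegetation, urban, barren, water. How a source
#' product's classes collapse onto these types is the caller's choice; the
#' legend only fixes the id <-> name mapping.
#'
#' @param ids integer ids, one per type, unique.
#' @param names character names; must be a permutation of the seven types.
#' @return object of class `class_legend`: named integer vector (name -> id).
#' @export
class_legend <- function(ids = 1:7, names = .functional_types) {
  if (length(ids) != 7L || length(names) != 7L) stop("legend needs exactly 7 entries")
  if (anyDuplicated(ids)) stop("class ids must be unique")
  if (!setequal(names, .functional_types))
    stop("legend names must be the seven functional types")
  out <- as.integer(ids)
  names(out) <- names
  structure(out, class = "class_legend")
}

#' @rdname class_legend
#' @export
default_legend <- function() class_legend()

class_id <- function(legend, name) unname(legend[name])
class_name <- function(legend, id) names(legend)[match(id, legend)]

#' Natural (semi-natural habitat capable) classes
#' @param legend a [class_legend()].
#' @return integer ids of forest, non-forest vegetation and grassland.
#' @export
natural_classes <- function(legend = default_legend()) {
  unname(legend[c("forest", "non_forest_vegetation", "grassland")])
}

# --- raster containers -----------------------------------------------------

#' Categorical (land-cover) raster
#'
#' @param values integer matrix of class ids, dimensions matching `spec`.
#' @param spec a [grid_spec()].
#' @param legend a [class_legend()].
#' @return object of class `lc_raster`.
#' @export
categorical_raster <- function(values, spec, legend = default_legend()) {
  values <- matrix(as.integer(values), spec$n_rows, spec$n_cols)
  if (!all(values %in% legend)) stop("raster contains values absent from the legend")
  structure(list(values = values, spec = spec, legend = legend),
            class = "lc_raster")
}

#' Continuous raster
#'
#' @param values numeric matrix; `NA` encodes nodata.
#' @param spec a [grid_spec()].
#' @param units free-text unit string.
#' @return object of class `num_raster`.
#' @export
continuous_raster <- function(values, spec, units = "") {
  values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values must be encoded as NA")
  structure(list(values = values, spec = spec, units = units),
            class = "num_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  tab <- table(factor(class_name(x$legend, x$values), levels = names(x$legend)))
  cat("lc_raster", x$spec$n_rows, "x", x$spec$n_cols, "\n")
  print(round(tab / length(x$values), 3))
  invisible(x)
}

#' @export
print.num_raster <- function(x, ...) {
  cat(sprintf("num_raster %d x %d [%s], range %.4g..%.4g\n",
              x$spec$n_rows, x$spec$n_cols, x$units,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

same_grid <- function(a, b) identical(unclass(a$spec), unclass(b$spec))

# --- cell areas ------------------------------------------------------------

#' Pixel-area model
#'
#' Converts pixels to hectares. `uniform` mode assigns every pixel the same
#' area (the default for controlled experiments: it removes latitude effects);
#' `spherical` mode computes the true area of the lon/lat quad on a sphere.
#'
#' @param mode `"uniform"` or `"spherical"`.
#' @param uniform_area ha per pixel in uniform mode (> 0).
#' @param earth_radius sphere radius in metres (spherical mode).
#' @return object of class `cell_area_model`.
#' @export
cell_area_model <- function(mode = c("uniform", "spherical"),
                            uniform_area = 9, earth_radius = 6371000) {
  mode <- match.arg(mode)
  if (mode == "uniform" && uniform_area <= 0) stop("uniform_area must be > 0")
  if (mode == "spherical" && earth_radius <= 0) stop("earth_radius must be > 0")
  structure(list(mode = mode, uniform_area = uniform_area,
                 earth_radius = earth_radius),
            class = "cell_area_model")
}

#' Per-row pixel areas in hectares
#'
#' Spherical mode: the area of a pixel bounded by latitudes \eqn{\phi_t >
#' \phi_b} and spanning \eqn{\Delta\lambda} of longitude is
#' \eqn{R^2 \Delta\lambda (\sin\phi_t - \sin\phi_b)} (in m^2, converted to ha).
#' Row areas therefore decrease towards the poles.
#'
#' @param spec a [grid_spec()].
#' @param model a [cell_area_model()].
#' @return numeric vector of length `n_rows`: ha per pixel in each row.
#' @export
cell_areas <- function(spec, model = cell_area_model()) {
  if (model$mode == "uniform") return(rep(model$uniform_area, spec$n_rows))
  i <- seq_len(spec$n_rows) - 1L
  lat_top <- (spec$origin_lat - i * spec$pixel_size) * pi / 180
  lat_bot <- (spec$origin_lat - (i + 1L) * spec$pixel_size) * pi / 180
  dlam <- spec$pixel_size * pi / 180
  m2 <- model$earth_radius^2 * dlam * (sin(lat_top) - sin(lat_bot))
  if (any(m2 <= 0)) stop("grid crosses a pole or has zero-area rows")
  m2 / 1e4
}

#' Matrix of per-pixel areas
#' @inheritParams cell_areas
#' @return numeric matrix `n_rows x n_cols` of ha per pixel.
#' @export
pixel_area_matrix <- function(spec, model = cell_area_model()) {
  matrix(cell_areas(spec, model), spec$n_rows, spec$n_cols)
}

# --- coarse tables ---------------------------------------------------------

#' Coarse per-cell, per-class area table
#'
#' Stores per-coarse-cell land areas (ha) as an `n_cells x 7` matrix with
#' class-name columns. Cells are numbered row-major over the coarse grid
#' (cell 1 = north-west corner).
#'
#' @param area numeric matrix `n_cells x 7`, columns named by class.
#' @param spec the fine [grid_spec()].
#' @param legend a [class_legend()].
#' @return object of class `coarse_state`.
#' @export
coarse_state <- function(area, spec, legend = default_legend()) {
  cd <- coarse_dims(spec)
  if (nrow(area) != prod(cd) || ncol(area) != 7L)
    stop("area must be n_cells x 7")
  if (is.null(colnames(area))) colnames(area) <- names(legend)
  if (any(area < -1e-9)) stop("areas must be >= 0")
  structure(list(area = area, spec = spec, legend = legend),
            class = "coarse_state")
}

#' Signed per-cell, per-class area changes
#'
#' @param delta numeric matrix `n_cells x 7` of signed ha deltas; per-cell
#'   sums must be ~0 (area conservation).
#' @param spec the fine [grid_spec()].
#' @param legend a [class_legend()].
#' @param year_from,year_to optional bracketing years (metadata).
#' @return object of class `coarse_changes`.
#' @export
coarse_changes <- function(delta, spec, legend = default_legend(),
                           year_from = NA, year_to = NA) {
  cd <- coarse_dims(spec)
  if (nrow(delta) != prod(cd) || ncol(delta) != 7L)
    stop("delta must be n_cells x 7")
  if (is.null(colnames(delta))) colnames(delta) <- names(legend)
  rs <- rowSums(delta)
  if (any(abs(rs) > 1e-6 * pmax(1, rowSums(abs(delta)))))
    stop("per-cell deltas must sum to 0")
  structure(list(delta = delta, spec = spec, legend = legend,
                 year_from = year_from, year_to = year_to),
            class = "coarse_changes")
}

#' @export
as.data.frame.coarse_state <- function(x, ...) {
  cd <- coarse_dims(x$spec)
  idx <- seq_len(prod(cd))
  data.frame(cell_id = rep(idx, 7L),
             row = rep((idx - 1L) %/% cd[2] + 1L, 7L),
             col = rep((idx - 1L) %% cd[2] + 1L, 7L),
             class = rep(colnames(x$area), each = length(idx)),
             area_ha = as.vector(x$area))
}

# block-sum a fine matrix into coarse cells (nI x nJ)
coarse_sum <- function(m, f) {
  nI <- nrow(m) %/% f
  nJ <- ncol(m) %/% f
  ig <- rep(seq_len(nI), each = f)
  jg <- rep(seq_len(nJ), each = f)
  t(rowsum(t(rowsum(m, ig, reorder = FALSE)), jg, reorder = FALSE))
}

#' Aggregate a fine land-cover map to a coarse area table
#'
#' The inverse of downscaling: sums member-pixel areas per coarse cell and
#' class. Used for conservation checks and as the coarse baseline state.
#'
#' @param lc a [categorical_raster()].
#' @param model a [cell_area_model()].
#' @return a [coarse_state()].
#' @export
aggregate_to_coarse <- function(lc, model = cell_area_model()) {
  spec <- lc$spec
  f <- spec$coarse_factor
  aremat <- pixel_area_matrix(spec, model)
  cd <- coarse_dims(spec)
  out <- matrix(0, prod(cd), 7L, dimnames = list(NULL, names(lc$legend)))
  for (k in seq_along(lc$legend)) {
    cmat <- coarse_sum(aremat * (lc$values == lc$legend[k]), f)
    # coarse_sum returns nI x nJ; flatten row-major to match cell numbering
    out[, names(lc$legend)[k]] <- as.vector(t(cmat))
  }
  coarse_state(out, spec, lc$legend)
}

#' Per-coarse-cell total areas (ha)
#' @inheritParams aggregate_to_coarse
#' @param spec a [grid_spec()].
#' @return numeric vector over cells (row-major coarse order).
#' @export
coarse_cell_areas <- function(spec, model = cell_area_model()) {
  aremat <- pixel_area_matrix(spec, model)
  as.vector(t(coarse_sum(aremat, spec$coarse_factor)))
}

# expand a coarse (nI x nJ) matrix to the fine grid
expand_coarse <- function(cm, spec) {
  f <- spec$coarse_factor
  cm[rep(seq_len(nrow(cm)), each = f), rep(seq_len(ncol(cm)), each = f)]
}

#' Coarse-cell id of every fine pixel
#'
#' @param spec a [grid_spec()].
#' @return integer fine matrix; cell ids are row-major over the coarse grid.
#' @export
cell_id_matrix <- function(spec) {
  cd <- coarse_dims(spec)
  ids <- matrix(seq_len(prod(cd)), cd[1], cd[2], byrow = TRUE)
  expand_coarse(ids, spec)
}

# --- plain-text raster I/O -------------------------------------------------

#' Write / read rasters as ESRI ASCII grid
#'
#' Plain-text single-band raster exchange. Categorical rasters get a YAML
#' legend sidecar (`<file>.legend.yml`) recording the id -> name mapping and
#' the coarse factor.
#'
#' @param x an `lc_raster` or `num_raster`.
#' @param file path of the `.asc` file to write.
#' @export
write_asc <- function(x, file) {
  spec <- x$spec
  v <- x$values
  nodata <- -9999
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", spec$n_cols),
           sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.10g", spec$origin_lon),
           sprintf("yllcorner %.10g", spec$origin_lat - spec$n_rows * spec$pixel_size),
           sprintf("cellsize %.10g", spec$pixel_size),
           sprintf("NODATA_value %d", nodata))
  writeLines(c(hdr, apply(v, 1, paste, collapse = " ")), file)
  if (inherits(x, "lc_raster")) {
    yaml::write_yaml(list(legend = as.list(stats::setNames(as.integer(x$legend), names(x$legend))),
                          coarse_factor = spec$coarse_factor),
                     paste0(file, ".legend.yml"))
  }
  invisible(file)
}

#' @rdname write_asc
#' @param coarse_factor coarse factor to attach when no sidecar is present.
#' @param categorical read as `lc_raster` (requires a legend sidecar or the
#'   default legend to apply)?
#' @export
read_asc <- function(file, coarse_factor = NULL, categorical = FALSE) {
  lines <- readLines(file)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(hdr[i], " +")[[1]][2])
  nc <- as.integer(val(1)); nr <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  v <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
              nr, nc, byrow = TRUE)
  v[v == nodata] <- NA
  side <- paste0(file, ".legend.yml")
  legend <- default_legend()
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    legend <- class_legend(unlist(y$legend), names(y$legend))
    if (is.null(coarse_factor)) coarse_factor <- y$coarse_factor
  }
  if (is.null(coarse_factor)) coarse_factor <- 2L
  spec <- grid_spec(origin_lon = xll, origin_lat = yll + nr * cs,
                    pixel_size = cs, n_rows = nr, n_cols = nc,
                    coarse_factor = coarse_factor)
  if (categorical) categorical_raster(v, spec, legend)
  else continuous_raster(v, spec)
}
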