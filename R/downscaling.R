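# shift a matrix by (di, dj), exposing NA where the shift leaves the map
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  ok_r <- ri >= 1L & ri <= nr
  ok_c <- cj >= 1L & cj <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
  out
}

#' Terrain roughness index from a DEM
#'
#' TRI of a pixel is the root-sum-of-squares of elevation differences to its
#' 8 neighbours; edge pixels use the neighbours that exist. Invariant under
#' adding a constant to the DEM.
#'
#' @param dem a [continuous_raster()] of elevations (m).
#' @return a [continuous_raster()] of TRI values (m).
#' @export
compute_tri <- function(dem) {
  z <- dem$values
  if (all(is.na(z))) stop("DEM is all nodata")
  acc <- matrix(0, nrow(z), ncol(z))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    d <- shift_mat(z, di, dj) - z
    d[is.na(d)] <- 0
    acc <- acc + d^2
  }
  continuous_raster(sqrt(acc), dem$spec, "m")
}

#' Per-class allocation parameters
#'
#' Adjacency weights and kernel widths (near/far truncated-Gaussian scales,
#' in pixels) plus physical-suitability weights for SOC and inverse terrain
#' roughness, one row per functional class. Scalars are recycled across
#' classes.
#'
#' @param w_near,w_far adjacency weights (>= 0) of the near and far kernel.
#' @param sigma_near,sigma_far kernel widths in pixels; `sigma_near <
#'   sigma_far`, both > 0.
#' @param a_soc,b_tri physical-suitability weights on normalised SOC and on
#'   (1 - normalised TRI).
#' @param legend a [class_legend()].
#' @return data.frame of class `alloc_params`, row-named by class.
#' @export
alloc_params <- function(w_near = 1, w_far = 0.3, sigma_near = 2,
                         sigma_far = 8, a_soc = 0.3, b_tri = 0.2,
                         legend = default_legend()) {
  rec <- function(x) rep_len(x, 7L)
  p <- data.frame(w_near = rec(w_near), w_far = rec(w_far),
                  sigma_near = rec(sigma_near), sigma_far = rec(sigma_far),
                  a_soc = rec(a_soc), b_tri = rec(b_tri),
                  row.names = names(legend))
  if (any(p$sigma_near <= 0) || any(p$sigma_far <= 0))
    stop("kernel widths must be > 0")
  if (any(p$sigma_near >= p$sigma_far))
    stop("sigma_near must be < sigma_far")
  if (any(p$w_near < 0) || any(p$w_far < 0))
    stop("adjacency weights must be >= 0")
  class(p) <- c("alloc_params", "data.frame")
  p
}

#' Adjacency surface for one class
#'
#' Measures the pull of existing pixels of a class on nearby locations,
#' capturing both distance and agglomeration: the class indicator is
#' smoothed with two isotropic truncated-Gaussian kernels (radius 3 sigma,
#' normalised to unit mass, boundary-renormalised over in-map mass) and the
#' two fields combined as `w_near * near + w_far * far`. A map entirely of
#' the class therefore scores `w_near + w_far` everywhere.
#'
#' @param lc a [categorical_raster()].
#' @param class name or id of the class.
#' @param params an [alloc_params()] table.
#' @return a [continuous_raster()] (dimensionless).
#' @export
adjacency_surface <- function(lc, class, params = alloc_params()) {
  cname <- if (is.character(class)) class else class_name(lc$legend, class)
  if (!cname %in% names(lc$legend)) stop("class not in legend")
  p <- params[cname, ]
  ind <- (lc$values == class_id(lc$legend, cname)) * 1
  s <- p$w_near * smooth_mat(ind, p$sigma_near) +
    p$w_far * smooth_mat(ind, p$sigma_far)
  continuous_raster(s, lc$spec, "")
}

# min-max normalisation over non-NA pixels; constant field -> 0.5
minmax01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) return(ifelse(is.na(m), NA, 0.5))
  (m - rng[1]) / diff(rng)
}

#' Physical suitability for one class
#'
#' Combines min-max-normalised soil organic carbon and inverse normalised
#' terrain roughness: `S = a_soc * soc01 + b_tri * (1 - tri01)`. A constant
#' input normalises to 0.5 by convention.
#'
#' @param soc,tri [continuous_raster()] layers on the same grid.
#' @param class class name or id.
#' @param params an [alloc_params()] table.
#' @return a [continuous_raster()].
#' @export
physical_suitability <- function(soc, tri, class, params = alloc_params()) {
  if (!same_grid(soc, tri)) stop("soc and tri grids differ")
  legend <- default_legend()
  cname <- if (is.character(class)) class else class_name(legend, class)
  p <- params[cname, ]
  s <- p$a_soc * minmax01(soc$values) + p$b_tri * (1 - minmax01(tri$values))
  continuous_raster(s, soc$spec, "")
}

#' Default allowed-transition matrix
#'
#' Logical 7 x 7 matrix `[from, to]`. Water and urban are terminal (never
#' sources) and water is never a target; cropland may expand into any
#' natural or barren land; forest may regrow on cropland, grassland and
#' non-forest vegetation; barren is never created. Fully overridable.
#'
#' @param legend a [class_legend()].
#' @return logical matrix with class-name dimnames.
#' @export
transition_defaults <- function(legend = default_legend()) {
  n <- names(legend)
  m <- matrix(FALSE, 7, 7, dimnames = list(from = n, to = n))
  m[c("grassland", "forest", "non_forest_vegetation", "barren"), "cropland"] <- TRUE
  m[c("cropland", "grassland", "non_forest_vegetation"), "forest"] <- TRUE
  m[c("cropland", "forest", "non_forest_vegetation"), "grassland"] <- TRUE
  m[c("cropland", "grassland", "forest", "barren"), "non_forest_vegetation"] <- TRUE
  m[c("cropland", "grassland", "non_forest_vegetation", "barren"), "urban"] <- TRUE
  diag(m) <- FALSE
  m
}

#' Conversion-eligibility rules
#'
#' Bundles the allowed-transition matrix with the protection mask. A pixel
#' of class `f` may convert to class `g` iff `transitions[f, g]` is `TRUE`
#' and, when the pixel is protected, neither `g` is cropland/urban nor `f`
#' is a natural class (protected natural land can never be lost; protected
#' land never gains cropland or urban).
#'
#' @param lc a [categorical_raster()] (legend reference).
#' @param protected logical fine matrix (or `NULL` for none).
#' @param transitions logical 7 x 7 `[from, to]` matrix, see
#'   [transition_defaults()].
#' @return object of class `eligibility`.
#' @export
build_eligibility <- function(lc, protected = NULL,
                              transitions = transition_defaults(lc$legend)) {
  if (is.null(protected))
    protected <- matrix(FALSE, lc$spec$n_rows, lc$spec$n_cols)
  stopifnot(identical(dim(protected), dim(lc$values)))
  structure(list(transitions = transitions, protected = protected,
                 legend = lc$legend),
            class = "eligibility")
}

#' Mask of pixels that may convert to a class
#'
#' @param elig an [build_eligibility()] object.
#' @param lc current [categorical_raster()].
#' @param class target class name or id.
#' @return logical matrix.
#' @export
target_mask <- function(elig, lc, class) {
  legend <- elig$legend
  gname <- if (is.character(class)) class else class_name(legend, class)
  fidx <- match(lc$values, legend)  # class index per pixel
  ok <- matrix(elig$transitions[, gname][fidx], nrow(lc$values))
  nat <- names(legend) %in% c("forest", "non_forest_vegetation", "grassland")
  if (gname %in% c("cropland", "urban")) ok <- ok & !elig$protected
  ok & !(elig$protected & matrix(nat[fidx], nrow(lc$values)))
}

#' Overall suitability stack
#'
#' Per class, the sum of the adjacency surface and the physical-suitability
#' surface; pixels ineligible as targets for the class carry `-Inf`.
#'
#' @param lc a [categorical_raster()].
#' @param soc SOC [continuous_raster()].
#' @param tri TRI [continuous_raster()] (from [compute_tri()]).
#' @param params an [alloc_params()] table.
#' @param elig optional [build_eligibility()] object for the sentinel.
#' @return named list of 7 score matrices.
#' @export
suitability_stack <- function(lc, soc, tri, params = alloc_params(),
                              elig = NULL) {
  out <- vector("list", 7L)
  names(out) <- names(lc$legend)
  for (cname in names(lc$legend)) {
    s <- adjacency_surface(lc, cname, params)$values +
      physical_suitability(soc, tri, cname, params)$values
    if (!is.null(elig)) s[!target_mask(elig, lc, cname)] <- -Inf
    out[[cname]] <- s
  }
  out
}

# signed largest-remainder rounding: reals summing to ~0 -> integers summing 0
round_preserving_zero <- function(x) {
  base <- floor(x)
  rem <- x - base
  k <- round(sum(rem))
  add <- integer(length(x))
  if (k > 0) add[order(rem, decreasing = TRUE)[seq_len(k)]] <- 1L
  as.integer(base) + add
}

infeasible_error <- function(msg, deficits) {
  stop(structure(class = c("landshift_infeasible", "error", "condition"),
                 list(message = paste0(msg, "\n",
                                       paste(utils::capture.output(print(deficits)),
                                             collapse = "\n")),
                      call = sys.call(-1), deficits = deficits)))
}

#' Allocate coarse land-cover changes to fine pixels
#'
#' The downscaling core. Per coarse cell, signed ha changes are converted to
#' pixel counts by largest-remainder rounding (counts sum to zero per cell).
#' Then, iteratively, the gaining class with the largest remaining demand
#' (ties: smallest class id) claims the eligible pixel with the highest
#' suitability score among pixels currently belonging to classes with
#' remaining loss demand (ties: first in row-major order). Allocation is
#' strictly per-cell; on success the aggregated result matches the rounded
#' targets exactly in pixel units. Infeasibility (no eligible candidate
#' while demand remains) raises an error carrying per-cell deficits; there
#' is never a silent partial allocation.
#'
#' @param lc0 baseline [categorical_raster()].
#' @param changes a [coarse_changes()] set.
#' @param stack a [suitability_stack()] built from `lc0`.
#' @param elig an [build_eligibility()] object.
#' @param model a [cell_area_model()].
#' @return list with `lc` (the new map), `report` (data.frame of
#'   conversions: cell, row, col, from, to, score) and `targets` (per
#'   cell/class pixel targets and residuals).
#' @export
allocate_changes <- function(lc0, changes, stack, elig,
                             model = cell_area_model()) {
  spec <- lc0$spec
  legend <- lc0$legend
  stopifnot(identical(unclass(spec), unclass(changes$spec)))
  f <- spec$coarse_factor
  cd <- coarse_dims(spec)
  aremat <- pixel_area_matrix(spec, model)
  vals <- lc0$values
  ids <- unname(legend)
  nat_idx <- names(legend) %in% c("forest", "non_forest_vegetation", "grassland")
  crop_urban <- names(legend) %in% c("cropland", "urban")
  conv <- list(); nconv <- 0L
  tgt_rows <- list()
  for (I in seq_len(cd[1])) for (J in seq_len(cd[2])) {
    cell <- (I - 1L) * cd[2] + J
    dha <- changes$delta[cell, ]
    if (all(dha == 0)) {
      tgt_rows[[cell]] <- data.frame(cell = cell, class = names(legend),
                                     target_px = 0L, allocated_px = 0L,
                                     residual = 0L)
      next
    }
    ri <- ((I - 1L) * f + 1L):(I * f)
    cj <- ((J - 1L) * f + 1L):(J * f)
    pos <- cbind(rep(ri, each = f), rep(cj, times = f))  # row-major
    pa <- mean(aremat[pos])
    dpx <- round_preserving_zero(dha / pa)
    cls <- match(vals[pos], ids)
    counts <- tabulate(cls, 7L)
    if (any(counts + dpx < 0L))
      infeasible_error("change drives a class below zero pixels",
                       data.frame(cell = cell, class = names(legend),
                                  have = counts, delta = dpx)[counts + dpx < 0L, ])
    gain <- pmax(dpx, 0L)
    loss <- pmax(-dpx, 0L)
    target_px <- dpx
    alloc_px <- integer(7L)
    prot_p <- elig$protected[pos]
    sc <- lapply(names(legend), function(g) stack[[g]][pos])
    while (sum(gain) > 0L) {
      g <- which.max(gain)  # first max = smallest class index
      cand <- loss[cls] > 0L & elig$transitions[cbind(cls, g)] &
        !(prot_p & (crop_urban[g] | nat_idx[cls]))
      if (!any(cand))
        infeasible_error("no eligible pixel for remaining demand",
                         data.frame(cell = cell, class = names(legend),
                                    remaining_gain = gain, remaining_loss = loss))
      s <- sc[[g]]
      s[!cand] <- -Inf
      best <- which.max(s)  # first max = row-major tie-break
      from <- cls[best]
      nconv <- nconv + 1L
      conv[[nconv]] <- c(cell, pos[best, 1L], pos[best, 2L], from, g, s[best])
      cls[best] <- g
      gain[g] <- gain[g] - 1L
      loss[from] <- loss[from] - 1L
      alloc_px[g] <- alloc_px[g] + 1L
      alloc_px[from] <- alloc_px[from] - 1L
    }
    vals[pos] <- ids[cls]
    tgt_rows[[cell]] <- data.frame(cell = cell, class = names(legend),
                                   target_px = target_px,
                                   allocated_px = alloc_px,
                                   residual = target_px - alloc_px)
  }
  report <- if (nconv > 0L) {
    m <- do.call(rbind, conv)
    data.frame(cell = as.integer(m[, 1]), row = as.integer(m[, 2]),
               col = as.integer(m[, 3]),
               from = names(legend)[m[, 4]], to = names(legend)[m[, 5]],
               score = m[, 6])
  } else {
    data.frame(cell = integer(), row = integer(), col = integer(),
               from = character(), to = character(), score = numeric())
  }
  targets <- do.call(rbind, tgt_rows)
  stopifnot(all(targets$residual == 0L))
  list(lc = categorical_raster(vals, spec, legend), report = report,
       targets = targets)
}

#' Allocation loss against observed change
#'
#' The fraction of truly or predictedly changed pixels that the prediction
#' gets wrong: `|pred != obs| / |{pred != baseline} union {obs != baseline}|`,
#' 0 when nothing changed in either map. 0 means every changed pixel was
#' placed correctly; 1 means all change was missed.
#'
#' @param pred,obs,baseline co-registered [categorical_raster()]s.
#' @return loss in \[0, 1\].
#' @export
allocation_loss <- function(pred, obs, baseline) {
  if (!same_grid(pred, obs) || !same_grid(pred, baseline))
    stop("grids differ")
  denom <- sum(pred$values != baseline$values | obs$values != baseline$values)
  if (denom == 0L) return(0)
  sum(pred$values != obs$values) / denom
}

#' Calibrate allocation parameters on withheld data
#'
#' Grid-search calibration: every candidate parameter set is used to re-run
#' the allocator over the holdout change series, starting from the last
#' observed fit-period map, and the candidate minimising [allocation_loss()]
#' on the final holdout map is returned (ties: first candidate). A candidate
#' for which allocation is infeasible scores loss 1.
#'
#' @param candidates list of [alloc_params()] tables.
#' @param baseline starting [categorical_raster()] (used when `fit_obs` is
#'   empty).
#' @param fit_changes,fit_obs fit-period change sets and observed maps (the
#'   last observed fit map seeds the holdout run).
#' @param holdout_changes,holdout_obs holdout-period change sets and
#'   observed maps.
#' @param covs a [gen_covariates()] set.
#' @param model a [cell_area_model()].
#' @param transitions allowed-transition matrix.
#' @param protected optional fine protection matrix.
#' @return list with `params` (winning candidate), `loss` (its holdout
#'   loss), `losses` (per-candidate) and `index`.
#' @export
calibrate_allocation <- function(candidates, baseline, fit_changes, fit_obs,
                                 holdout_changes, holdout_obs, covs,
                                 model = cell_area_model(),
                                 transitions = transition_defaults(),
                                 protected = NULL) {
  if (length(candidates) == 0L) stop("empty candidate grid")
  start <- if (length(fit_obs) > 0L) fit_obs[[length(fit_obs)]] else baseline
  obs_final <- holdout_obs[[length(holdout_obs)]]
  losses <- vapply(candidates, function(p) {
    maps <- tryCatch(
      gen_history(p, start, holdout_changes, covs, model, transitions,
                  protected),
      landshift_infeasible = function(e) NULL)
    if (is.null(maps)) return(1)
    allocation_loss(maps[[length(maps)]], obs_final, start)
  }, numeric(1))
  i <- which.min(losses)
  list(params = candidates[[i]], loss = losses[i], losses = losses, index = i)
}
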