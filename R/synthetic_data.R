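#' Configuration for the synthetic landscape generator
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param class_mix named numeric vector of target class fractions (names
#'   from the 7-type legend); must be non-negative and sum to 1. The order of
#'   the names controls which classes end up spatially adjacent (consecutive
#'   bands of the underlying random field), so the default orders classes
#'   along a plausible water - forest - shrub - grassland - cropland - urban
#'   - barren gradient.
#' @param autocorrelation_length spatial correlation scale in pixels (>= 1).
#' @param spec a [grid_spec()].
#' @return object of class `landscape_gen_config`.
#' @export
landscape_gen_config <- function(seed = 1L,
                                 class_mix = c(water = 0.06, forest = 0.25,
                                               non_forest_vegetation = 0.10,
                                               grassland = 0.15,
                                               cropland = 0.35, urban = 0.04,
                                               barren = 0.05),
                                 autocorrelation_length = 6,
                                 spec = grid_spec()) {
  if (any(class_mix < 0)) stop("class_mix fractions must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% .functional_types))
    stop("class_mix names must be functional types")
  if (autocorrelation_length < 1) stop("autocorrelation_length must be >= 1")
  structure(list(seed = as.integer(seed), class_mix = class_mix,
                 autocorrelation_length = autocorrelation_length,
                 spec = spec),
            class = "landscape_gen_config")
}

#' Generate a spatially autocorrelated synthetic land-cover map
#'
#' A neutral-landscape generator: white noise is smoothed with an isotropic
#' truncated-Gaussian kernel of width `autocorrelation_length` and the
#' resulting field is thresholded at the class-mix quantiles, so realised
#' class fractions match the requested mix to within one pixel. Deterministic
#' given the seed.
#'
#' @param cfg a [landscape_gen_config()].
#' @param legend a [class_legend()].
#' @return a [categorical_raster()].
#' @export
gen_landscape <- function(cfg, legend = default_legend()) {
  spec <- cfg$spec
  mix <- cfg$class_mix[cfg$class_mix > 0]
  withr::with_seed(cfg$seed, {
    n <- spec$n_rows * spec$n_cols
    if (length(mix) == 1L) {
      v <- matrix(class_id(legend, names(mix)), spec$n_rows, spec$n_cols)
      return(categorical_raster(v, spec, legend))
    }
    field <- random_field(spec$n_rows, spec$n_cols, cfg$autocorrelation_length)
    r <- rank(as.vector(field), ties.method = "first")
    cuts <- round(cumsum(mix) * n)
    cuts[length(cuts)] <- n
    band <- findInterval(r, cuts[-length(cuts)], left.open = TRUE) + 1L
    ids <- unname(legend[names(mix)])
    categorical_raster(matrix(ids[band], spec$n_rows, spec$n_cols),
                       spec, legend)
  })
}

#' Generate synthetic covariates for a domain
#'
#' Produces smooth, seeded stand-ins for the environmental layers the
#' indicator models consume: soil organic carbon, elevation, rainfall
#' erosivity, soil texture and organic-carbon percentages, tree and
#' vegetation fractional cover, per-coarse-cell crop-group shares (Dirichlet
#' over 20 groups), potential-cropland areas, region ids, a contiguous
#' conservation template, a boreal mask, and potential-vegetation carbon
#' density.
#'
#' @param seed integer seed.
#' @param spec a [grid_spec()].
#' @param model a [cell_area_model()] (for cell areas behind
#'   `potential_cropland`).
#' @param template_frac fraction of coarse cells in the conservation
#'   template (contiguous high values of a smooth coarse field).
#' @param boreal_frac fraction of northernmost coarse rows flagged boreal.
#' @param n_crop_groups number of crop groups (default 20).
#' @return object of class `covariate_set` (see fields in source).
#' @export
gen_covariates <- function(seed, spec, model = cell_area_model(),
                           template_frac = 0.25, boreal_frac = 0.15,
                           n_crop_groups = 20L) {
  cd <- coarse_dims(spec)
  n_cells <- prod(cd)
  nr <- spec$n_rows; nc <- spec$n_cols
  withr::with_seed(seed, {
    z <- function(sig = 6) random_field(nr, nc, sig)
    zc <- function(sig = 1.5) random_field(cd[1], cd[2], sig)
    soc <- continuous_raster(40 * exp(0.5 * z()), spec, "t C ha-1")
    dem <- continuous_raster(300 + 150 * z(8) + 25 * z(2), spec, "m")
    eros <- continuous_raster(2000 * exp(0.4 * z()), spec,
                              "MJ mm ha-1 h-1 yr-1")
    g1 <- exp(0.8 * z()); g2 <- exp(0.8 * z()); g3 <- exp(0.8 * z())
    tot <- g1 + g2 + g3
    sand <- continuous_raster(100 * g1 / tot, spec, "%")
    silt <- continuous_raster(100 * g2 / tot, spec, "%")
    clay <- continuous_raster(100 * g3 / tot, spec, "%")
    orgc <- continuous_raster(1.5 * exp(0.4 * z()), spec, "%")
    tree <- continuous_raster(stats::plogis(1.2 * z()), spec, "fraction")
    fcov <- continuous_raster(stats::plogis(1.0 * z()), spec, "fraction")
    shares <- matrix(stats::rgamma(n_cells * n_crop_groups, shape = 0.5),
                     n_cells, n_crop_groups)
    shares <- shares / rowSums(shares)
    colnames(shares) <- paste0("crop_", seq_len(n_crop_groups))
    cell_area <- coarse_cell_areas(spec, model)
    potc <- (0.55 + 0.35 * stats::plogis(as.vector(t(zc())))) * cell_area
    region <- as.vector(t(outer(seq_len(cd[1]) > cd[1] / 2,
                                seq_len(cd[2]) > cd[2] / 2,
                                function(a, b) 1L + a * 2L + b * 1L)))
    tmpl_field <- as.vector(t(zc()))
    k <- max(1L, round(template_frac * n_cells))
    template <- tmpl_field >= sort(tmpl_field, decreasing = TRUE)[k]
    boreal <- rep(seq_len(cd[1]) <= max(1L, floor(boreal_frac * cd[1])),
                  each = cd[2])
    potveg <- 5 + 120 * stats::plogis(2 * as.vector(t(zc())))
    structure(list(spec = spec, soc = soc, dem = dem, erosivity_R = eros,
                   sand = sand, silt = silt, clay = clay, orgC = orgc,
                   tree_cover = tree, fcover = fcov, crop_shares = shares,
                   potential_cropland = potc, region_id = region,
                   protected_template = template, boreal = boreal,
                   potveg_carbon = potveg, seed = as.integer(seed)),
              class = "covariate_set")
  })
}

#' Scenario demand configuration
#'
#' Free parameters of the synthetic coarse demand generator. The magnitudes
#' of land-cover change emerge from an out-of-scope economic model, so they
#' are configuration here: a per-step relative cropland expansion rate, a
#' multiplier (< 1) applied under climate policy, and a per-step
#' reforestation area demand under climate policy.
#'
#' @param years strictly increasing simulation years (default 2015..2050 in
#'   5-year steps).
#' @param cropland_expansion_rate fractional cropland growth per step.
#' @param coaction_expansion_multiplier factor in (0, 1] applied to the
#'   expansion rate when climate policy is active.
#' @param reforestation_demand ha of reforestation per step under climate
#'   policy; `NULL` means 0.4\% of the domain's land area per step.
#' @param seed integer seed (protection ordering and any stochastic choices).
#' @return object of class `scenario_demand_config`.
#' @export
scenario_demand_config <- function(years = seq(2015, 2050, by = 5),
                                   cropland_expansion_rate = 0.09,
                                   coaction_expansion_multiplier = 0.2,
                                   reforestation_demand = NULL,
                                   seed = 1L) {
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (coaction_expansion_multiplier <= 0 || coaction_expansion_multiplier > 1)
    stop("coaction_expansion_multiplier must be in (0, 1]")
  structure(list(years = years,
                 cropland_expansion_rate = cropland_expansion_rate,
                 coaction_expansion_multiplier = coaction_expansion_multiplier,
                 reforestation_demand = reforestation_demand,
                 seed = as.integer(seed)),
            class = "scenario_demand_config")
}

#' Protected coarse cells at a given year
#'
#' The conservation template is phased in along a seeded deterministic
#' ordering of its cells: at template fraction f, the first `ceiling(f * n)`
#' cells of that ordering are protected.
#'
#' @param covs a [gen_covariates()] set (provides the template).
#' @param scen a [scenario_preset()].
#' @param seed integer seed fixing the phase-in ordering.
#' @param year evaluation year.
#' @return logical vector over coarse cells (row-major).
#' @export
protected_cells <- function(covs, scen, seed, year) {
  n_cells <- length(covs$protected_template)
  out <- rep(FALSE, n_cells)
  if (!isTRUE(scen$area_based_conservation)) return(out)
  f <- protection_schedule(year, scen$protection_years)$fraction
  tmpl <- which(covs$protected_template)
  if (f <= 0 || length(tmpl) == 0L) return(out)
  ord <- withr::with_seed(seed, sample(tmpl))
  out[ord[seq_len(ceiling(f * length(tmpl)))]] <- TRUE
  out
}

# proportionally distribute `total` over cells by `weights`, capped at
# `capacity`; waterfilling until total placed or capacity exhausted
distribute_capped <- function(total, weights, capacity) {
  x <- numeric(length(weights))
  if (total <= 0) return(x)
  active <- capacity > 1e-12 & weights > 0
  remaining <- total
  while (remaining > 1e-9 && any(active)) {
    w <- ifelse(active, weights, 0)
    add <- pmin(remaining * w / sum(w), capacity - x)
    x <- x + add
    remaining <- total - sum(x)
    active <- (capacity - x) > 1e-9 & weights > 0
  }
  attr(x, "deficit") <- max(0, remaining)
  x
}

#' Generate coarse scenario change tables
#'
#' Emulates the demand side of a global land-system model at desk scale: per
#' 5-year step, cropland in each unprotected cell grows by the configured
#' rate (damped by the climate-policy multiplier when active) at the expense
#' of the cell's natural classes, subject to the 90\% availability constraint
#' and, under the landscape policy, the cap trajectory; climate policy
#' additionally places a reforestation demand on eligible cells (outside the
#' boreal zone, potential-vegetation carbon density > 20 t C/ha,
#' unprotected), sourced from grassland and non-forest vegetation; and under
#' the landscape policy cropland exceeding the cap is relocated to
#' under-cap unprotected cells without changing the global cropland total.
#' Every returned change set is feasible for the allocator by construction
#' (a one-pixel-per-class margin is kept on every losing class).
#'
#' @param baseline a [coarse_state()] (typically from
#'   [aggregate_to_coarse()]).
#' @param covs a [gen_covariates()] set.
#' @param scen a [scenario_preset()].
#' @param dem_cfg a [scenario_demand_config()].
#' @return list of [coarse_changes()], one per step, with `year_from` /
#'   `year_to` set.
#' @export
gen_coarse_scenario <- function(baseline, covs, scen, dem_cfg) {
  spec <- baseline$spec
  legend <- baseline$legend
  nat <- c("forest", "non_forest_vegetation", "grassland")
  state <- baseline$area
  n_cells <- nrow(state)
  cell_area <- rowSums(state)
  # per-class safety margin of a few fine pixels: keeps every generated loss
  # strictly below the class's pixel stock even after per-step rounding drift
  margin <- 4 * cell_area / spec$coarse_factor^2
  years <- dem_cfg$years
  refo <- dem_cfg$reforestation_demand
  if (is.null(refo)) refo <- 0.004 * sum(cell_area)
  out <- vector("list", length(years) - 1L)
  for (s in seq_len(length(years) - 1L)) {
    y1 <- years[s + 1L]
    prot <- protected_cells(covs, scen, dem_cfg$seed, y1)
    d <- matrix(0, n_cells, 7L, dimnames = list(NULL, names(legend)))
    rate <- dem_cfg$cropland_expansion_rate *
      if (isTRUE(scen$climate_policy)) dem_cfg$coaction_expansion_multiplier else 1
    avail_nat <- pmax(state[, nat, drop = FALSE] - margin, 0)
    ## cropland expansion
    want <- rate * state[, "cropland"]
    lim <- pmax(0, 0.9 * covs$potential_cropland - state[, "cropland"])
    if (isTRUE(scen$landscape_policy)) {
      capfrac <- policy_cap(y1, scen$cap_params)
      lim <- pmin(lim, pmax(0, capfrac * covs$potential_cropland -
                                 state[, "cropland"]))
    }
    dcrop <- pmin(want, lim, rowSums(avail_nat))
    dcrop[prot] <- 0
    dcrop[dcrop < 0] <- 0
    pos <- dcrop > 0
    if (any(pos)) {
      w <- avail_nat[pos, , drop = FALSE] /
        rowSums(avail_nat[pos, , drop = FALSE])
      d[pos, nat] <- d[pos, nat] - dcrop[pos] * w
      d[pos, "cropland"] <- d[pos, "cropland"] + dcrop[pos]
      avail_nat[pos, ] <- avail_nat[pos, ] - dcrop[pos] * w
    }
    ## reforestation under climate policy
    if (isTRUE(scen$climate_policy) && refo > 0) {
      src <- c("grassland", "non_forest_vegetation")
      elig <- !covs$boreal & covs$potveg_carbon > 20 & !prot
      conv <- rowSums(avail_nat[, src, drop = FALSE]) * elig
      placed <- distribute_capped(refo, conv, conv)
      if (attr(placed, "deficit") > 1e-6)
        stop("infeasible reforestation demand: deficit ",
             format(attr(placed, "deficit")), " ha")
      pos <- placed > 0
      if (any(pos)) {
        w <- avail_nat[pos, src, drop = FALSE] /
          rowSums(avail_nat[pos, src, drop = FALSE])
        d[pos, src] <- d[pos, src] - placed[pos] * w
        d[pos, "forest"] <- d[pos, "forest"] + placed[pos]
        avail_nat[pos, src] <- avail_nat[pos, src] - placed[pos] * w
      }
    }
    ## landscape policy: relocate cropland above the cap
    if (isTRUE(scen$landscape_policy) && y1 >= scen$cap_params$year_start) {
      post <- state + d
      capfrac <- policy_cap(y1, scen$cap_params)
      nat_avail_post <- pmax(0, rowSums(post[, nat, drop = FALSE]) - 3 * margin)
      rel <- relocate_excess(crop = post[, "cropland"],
                             potential = covs$potential_cropland,
                             cap = capfrac, protected = prot,
                             receiver_capacity = nat_avail_post)
      if (any(rel$removed > 0)) {
        d[, "cropland"] <- d[, "cropland"] - rel$removed + rel$received
        d[, "non_forest_vegetation"] <-
          d[, "non_forest_vegetation"] + rel$removed
        pos <- rel$received > 0
        if (any(pos)) {
          w <- post[pos, nat, drop = FALSE] /
            rowSums(post[pos, nat, drop = FALSE])
          d[pos, nat] <- d[pos, nat] - rel$received[pos] * w
        }
      }
    }
    state <- state + d
    out[[s]] <- coarse_changes(d, spec, legend,
                               year_from = years[s], year_to = y1)
  }
  out
}

#' Run the allocator over a change series with known parameters
#'
#' Produces an "observed" fine-map history by iteratively applying
#' [allocate_changes()] with given (true) allocation parameters; used as the
#' ground truth in calibration experiments.
#'
#' @param params an [alloc_params()] table.
#' @param baseline a [categorical_raster()] starting map.
#' @param changes list of [coarse_changes()].
#' @param covs a [gen_covariates()] set (SOC and DEM feed suitability).
#' @param model a [cell_area_model()].
#' @param transitions allowed-transition matrix, see
#'   [transition_defaults()].
#' @param protected optional fine logical matrix (constant over steps).
#' @return list of [categorical_raster()], one per step.
#' @export
gen_history <- function(params, baseline, changes, covs,
                        model = cell_area_model(),
                        transitions = transition_defaults(),
                        protected = NULL) {
  tri <- compute_tri(covs$dem)
  lc <- baseline
  out <- vector("list", length(changes))
  for (s in seq_along(changes)) {
    elig <- build_eligibility(lc, protected, transitions)
    stack <- suitability_stack(lc, covs$soc, tri, params, elig)
    lc <- allocate_changes(lc, changes[[s]], stack, elig, model)$lc
    out[[s]] <- lc
  }
  out
}
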