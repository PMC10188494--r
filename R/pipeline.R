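#' Pipeline configuration
#'
#' Single configuration tree for [run_scenario_pipeline()]. Defaults give a
#' desk-scale domain (100 x 100 fine pixels, coarse factor 20, 300 m pixels)
#' over the 2015-2050 horizon in 5-year steps with all four scenario
#' presets.
#'
#' @param spec a [grid_spec()].
#' @param seed master integer seed; the landscape, covariates and demand
#'   generator seeds are all derived from it.
#' @param scenarios character vector of preset names to run.
#' @param years simulation years.
#' @param class_mix landscape class mix (see [landscape_gen_config()]).
#' @param autocorrelation_length landscape correlation scale, pixels.
#' @param model a [cell_area_model()].
#' @param params an [alloc_params()] table for the allocator.
#' @param transitions allowed-transition matrix.
#' @param demand named list of overrides for [scenario_demand_config()].
#' @param pollination a [pollination_config()].
#' @param c_table a [c_factor_defaults()]-style C-factor table.
#' @param keep_maps keep per-step land-cover maps in the result?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = grid_spec(n_rows = 100, n_cols = 100,
                                             coarse_factor = 20),
                            seed = 1L,
                            scenarios = c("BAU", "PROTECT", "COACTION",
                                          "MULTI"),
                            years = seq(2015, 2050, by = 5),
                            class_mix = NULL,
                            autocorrelation_length = 6,
                            model = cell_area_model(),
                            params = alloc_params(),
                            transitions = transition_defaults(),
                            demand = list(),
                            pollination = pollination_config(),
                            c_table = c_factor_defaults(),
                            keep_maps = FALSE) {
  structure(list(spec = spec, seed = as.integer(seed), scenarios = scenarios,
                 years = years, class_mix = class_mix,
                 autocorrelation_length = autocorrelation_length,
                 model = model, params = params, transitions = transitions,
                 demand = demand, pollination = pollination,
                 c_table = c_table, keep_maps = keep_maps),
            class = "pipeline_config")
}

#' Run the full scenario pipeline
#'
#' Orchestrates simulate -> scenario -> downscale -> indicators for each
#' requested scenario preset on a shared synthetic domain: one landscape and
#' covariate set per seed, per-scenario coarse change tables, iterative
#' suitability-ranked allocation per time step, then pollination
#' sufficiency, soil loss and compositional-heterogeneity summaries at the
#' baseline and final year (historic-cropland figures use the baseline
#' cropland mask). Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return list of class `landshift_run` with elements `baseline` (map,
#'   coarse state, covariates), `scenarios` (per-preset results: final map,
#'   pollination / soil-loss / heterogeneity summaries, change tables) and
#'   `manifest` (seeds, years, wall-clock per stage).
#' @export
run_scenario_pipeline <- function(config = pipeline_config()) {
  spec <- config$spec
  model <- config$model
  gen_args <- list(seed = config$seed,
                   autocorrelation_length = config$autocorrelation_length,
                   spec = spec)
  if (!is.null(config$class_mix)) gen_args$class_mix <- config$class_mix
  lc0 <- gen_landscape(do.call(landscape_gen_config, gen_args))
  covs <- gen_covariates(config$seed + 7919L, spec, model)
  baseline <- aggregate_to_coarse(lc0, model)
  tri <- compute_tri(covs$dem)
  K <- k_from_soil(covs$sand, covs$silt, covs$clay, covs$orgC)
  LS <- ls_factor(covs$dem, spec)$ls
  historic <- lc0$values == class_id(lc0$legend, "cropland")
  indicators <- function(lc) {
    sc <- pollination_scores(lc, config$pollination)
    C <- c_factor(lc, covs$crop_shares, covs$tree_cover, covs$fcover,
                  config$c_table)
    A <- rusle_a(covs$erosivity_R, K, LS, C)
    soil <- aggregate_soil_loss(A, lc, covs$region_id, model,
                                historic = historic)
    list(scores = sc, soil = soil)
  }
  ind0 <- indicators(lc0)
  manifest <- list(seed = config$seed, years = config$years,
                   scenarios = config$scenarios,
                   grid = unclass(spec), stage_seconds = list())
  out <- list()
  for (nm in config$scenarios) {
    t_start <- proc.time()[["elapsed"]]
    scen <- scenario_preset(nm)
    dem_cfg <- do.call(scenario_demand_config,
                       utils::modifyList(list(years = config$years,
                                              seed = config$seed),
                                         config$demand))
    changes <- gen_coarse_scenario(baseline, covs, scen, dem_cfg)
    lc <- lc0
    maps <- if (config$keep_maps) vector("list", length(changes)) else NULL
    for (s in seq_along(changes)) {
      prot <- protected_cells(covs, scen, dem_cfg$seed, changes[[s]]$year_to)
      ids <- cell_id_matrix(spec)
      prot_fine <- matrix(prot[ids], nrow(ids), ncol(ids))
      elig <- build_eligibility(lc, prot_fine, config$transitions)
      stack <- suitability_stack(lc, covs$soc, tri, config$params, elig)
      lc <- allocate_changes(lc, changes[[s]], stack, elig, model)$lc
      if (config$keep_maps) maps[[s]] <- lc
    }
    ind1 <- indicators(lc)
    poll <- summarize_pollination(ind0$scores$s, ind1$scores$s, historic,
                                  model, config$pollination)
    final_state <- aggregate_to_coarse(lc, model)
    het <- cropland_fraction_bins(final_state, covs$potential_cropland)
    out[[nm]] <- list(
      scenario = scen, changes = changes, final_lc = lc, maps = maps,
      final_state = final_state, pollination = poll,
      soil = list(t0 = ind0$soil, t1 = ind1$soil),
      heterogeneity = het)
    manifest$stage_seconds[[nm]] <-
      round(proc.time()[["elapsed"]] - t_start, 2)
  }
  structure(list(baseline = list(lc = lc0, state = baseline, covs = covs,
                                 indicators = ind0),
                 scenarios = out, manifest = manifest),
            class = "landshift_run")
}

#' @export
print.landshift_run <- function(x, ...) {
  cat("landshift run: seed", x$manifest$seed, "-",
      paste(x$manifest$scenarios, collapse = ", "), "\n")
  for (nm in names(x$scenarios)) {
    r <- x$scenarios[[nm]]
    crop <- sum(r$final_state$area[, "cropland"])
    soil <- r$soil$t1$global[["all"]]
    cat(sprintf("  %-8s final cropland %.0f ha, soil loss %.3g Pg/yr\n",
                nm, crop, soil))
  }
  invisible(x)
}
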