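#' Scenario presets
#'
#' Four scenario archetypes combining three land-system interventions:
#' \describe{
#'   \item{BAU}{business as usual, no intervention.}
#'   \item{PROTECT}{area-based conservation only: a fixed spatial template of
#'     conservation-priority cells is phased in between 2020 and 2030, after
#'     which no further land conversion may occur inside it.}
#'   \item{COACTION}{conservation plus climate policy: a carbon price rising
#'     at 5\%/yr from 2025 drives reforestation outside the boreal zone where
#'     potential-vegetation carbon density exceeds 20 t C/ha, and strongly
#'     curbs cropland expansion into natural land.}
#'   \item{MULTI}{all of the above plus a landscape policy capping cropland
#'     at 90\% of a cell's potential cropland in 2025, tightening linearly to
#'     80\% by 2030, so that at least 20\% semi-natural habitat remains in
#'     farmed landscapes.}
#' }
#'
#' @param name one of `"BAU"`, `"PROTECT"`, `"COACTION"`, `"MULTI"`
#'   (case-insensitive, surrounding whitespace trimmed).
#' @param ... overrides for `protection_years`, `price_params`, `cap_params`.
#' @return object of class `scenario_config` with logical intervention flags
#'   and parameter lists.
#' @export
scenario_preset <- function(name, ...) {
  key <- toupper(trimws(name))
  presets <- list(
    BAU      = c(conservation = FALSE, climate = FALSE, landscape = FALSE),
    PROTECT  = c(conservation = TRUE,  climate = FALSE, landscape = FALSE),
    COACTION = c(conservation = TRUE,  climate = TRUE,  landscape = FALSE),
    MULTI    = c(conservation = TRUE,  climate = TRUE,  landscape = TRUE))
  if (!key %in% names(presets))
    stop("unknown scenario '", name, "'; use BAU, PROTECT, COACTION or MULTI")
  flags <- presets[[key]]
  cfg <- list(name = key,
              area_based_conservation = unname(flags["conservation"]),
              climate_policy = unname(flags["climate"]),
              landscape_policy = unname(flags["landscape"]),
              protection_years = list(start = 2020, full = 2030,
                                      primary_forest_full = 2025),
              price_params = list(p0 = 109.8, growth = 0.05, t0 = 2025),
              cap_params = list(cap_start = 0.90, year_start = 2025,
                                cap_end = 0.80, year_end = 2030))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  structure(cfg, class = "scenario_config")
}

#' Carbon price trajectory
#'
#' Compound growth from the policy start: \eqn{p(t) = p_0 (1+g)^{t-t_0}},
#' with defaults \eqn{p_0 = 109.8} USD/tCO2 at 2025 and \eqn{g = 0.05}/yr,
#' reaching 371.8 USD/tCO2 in 2050.
#'
#' @param year numeric year(s), must be `>= t0`.
#' @param price_params list with `p0`, `growth`, `t0`.
#' @return price(s) in USD per tCO2.
#' @export
carbon_price <- function(year, price_params = list(p0 = 109.8, growth = 0.05,
                                                   t0 = 2025)) {
  if (any(year < price_params$t0))
    stop("carbon price undefined before policy start (", price_params$t0, ")")
  price_params$p0 * (1 + price_params$growth)^(year - price_params$t0)
}

#' Landscape-policy cropland cap
#'
#' Maximum cropland fraction of a cell's potential cropland under the
#' landscape policy: 0.90 at 2025, falling linearly to 0.80 at 2030, constant
#' after. Before 2025 the policy is inactive (cap 1; the separate 90\%
#' availability constraint still applies to all scenarios).
#'
#' @param year numeric year(s).
#' @param cap_params list with `cap_start`, `year_start`, `cap_end`,
#'   `year_end`.
#' @return cap fraction(s) in (0, 1].
#' @export
policy_cap <- function(year, cap_params = list(cap_start = 0.90,
                                               year_start = 2025,
                                               cap_end = 0.80,
                                               year_end = 2030)) {
  with(cap_params, {
    frac <- pmin(pmax((year - year_start) / (year_end - year_start), 0), 1)
    ifelse(year < year_start, 1,
           cap_start + frac * (cap_end - cap_start))
  })
}

#' Conservation-template phase-in schedule
#'
#' Fraction of the conservation template under protection at a given year,
#' rising linearly from 0 at the schedule start (2020) to 1 at full
#' protection (2030), and a flag for full primary-forest protection (from
#' 2025). The linear interpolation is this package's reading of a gradual
#' phase-in; cells are protected in a seeded deterministic order so that a
#' fraction f protects the first `ceiling(f * n)` template cells.
#'
#' @param year numeric year(s).
#' @param protection_years list with `start`, `full`, `primary_forest_full`.
#' @return list with `fraction` (in \[0,1\]) and `primary_forest` (logical).
#' @export
protection_schedule <- function(year,
                                protection_years = list(start = 2020,
                                                        full = 2030,
                                                        primary_forest_full = 2025)) {
  with(protection_years, {
    frac <- pmin(pmax((year - start) / (full - start), 0), 1)
    list(fraction = frac, primary_forest = year >= primary_forest_full)
  })
}
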