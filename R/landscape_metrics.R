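#' Cropland fraction of potential cropland, binned
#'
#' Compositional-heterogeneity summary: per coarse cell the ratio of
#' cropland area to available potential cropland, and global cropland area
#' per fraction bin of width 0.2 (`[0, 0.2), ..., [0.8, 1]`). Fractions above
#' 1 (possible in input data) are clipped to 1 for binning only; the raw
#' value is retained. Cells in the top bin are the homogeneous landscapes.
#'
#' @param state a [coarse_state()].
#' @param potential_ha potential cropland per cell (ha), > 0 wherever
#'   cropland is present.
#' @return list with `per_cell` (data.frame cell/cropland_ha/potential_ha/
#'   fraction) and `bins` (data.frame bin/cropland_area_ha).
#' @export
cropland_fraction_bins <- function(state, potential_ha) {
  crop <- state$area[, "cropland"]
  if (any(crop > 0 & potential_ha <= 0))
    stop("cropland present in cells with zero potential cropland")
  frac <- ifelse(potential_ha > 0, crop / potential_ha, 0)
  fb <- pmin(frac, 1)
  bin <- pmin(findInterval(fb, seq(0, 0.8, 0.2)), 5L)  # [0.8, 1] closed top
  labs <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")
  area <- tapply(crop, factor(bin, levels = 1:5), sum)
  area[is.na(area)] <- 0
  list(per_cell = data.frame(cell = seq_along(crop), cropland_ha = crop,
                             potential_ha = potential_ha, fraction = frac),
       bins = data.frame(bin = labs, cropland_area_ha = as.numeric(area)))
}

# integer-ha relocation core: removals = ceiling(excess), receipts =
# capacity-capped largest-remainder proportional to slack; exact balance
relocate_excess <- function(crop, potential, cap, protected,
                            receiver_capacity = Inf) {
  excess <- pmax(0, crop - cap * potential)
  removed <- ceiling(pmax(0, excess - 1e-9))
  total <- sum(removed)
  received <- numeric(length(crop))
  if (total == 0) return(list(removed = removed, received = received))
  slack <- pmax(0, cap * potential - crop)
  eligible <- !protected & removed == 0 & slack > 0
  capacity <- floor(pmin(slack, receiver_capacity))
  capacity[!eligible] <- 0
  if (sum(capacity) < total)
    stop("insufficient global slack to relocate cropland: shortfall ",
         total - sum(capacity), " ha")
  remaining <- total
  while (remaining > 0L) {
    open <- capacity - received > 0 & slack > 0
    tgt <- remaining * slack * open / sum(slack * open)
    add <- pmin(floor(tgt), capacity - received)
    rem_frac <- tgt - floor(tgt)
    received <- received + add
    remaining <- total - sum(received)
    if (remaining > 0L) {
      # hand out the leftover hectares one by one, largest remainder first
      open_idx <- which(capacity - received > 0)
      ord <- open_idx[order(rem_frac[open_idx], decreasing = TRUE)]
      take <- ord[seq_len(min(remaining, length(ord)))]
      received[take] <- received[take] + 1
      remaining <- total - sum(received)
    }
  }
  list(removed = removed, received = received)
}

#' Apply the landscape policy to a coarse state
#'
#' Enforces the cropland cap by spatial relocation: each over-cap cell's
#' excess (rounded up to whole hectares, guaranteeing the cap) is converted
#' to a restoration class, and the pooled excess is reassigned to
#' unprotected under-cap cells proportionally to their slack
#' (capacity-capped largest-remainder rounding in whole hectares), sourced
#' from each receiving cell's natural classes proportionally. The global
#' cropland total is conserved exactly; protected cells receive nothing.
#'
#' @param state a [coarse_state()].
#' @param potential_ha potential cropland per cell (ha).
#' @param cap cap fraction (e.g. `policy_cap(2030)` = 0.80).
#' @param protected logical vector over coarse cells.
#' @param restore_class class receiving removed cropland (default
#'   non-forest vegetation: restoration of semi-natural habitat).
#' @return list with `state` (new [coarse_state()]) and `plan` (data.frame
#'   cell/removed_ha/received_ha plus `total_moved` attribute).
#' @export
apply_landscape_policy <- function(state, potential_ha, cap,
                                   protected = rep(FALSE, nrow(state$area)),
                                   restore_class = "non_forest_vegetation") {
  area <- state$area
  nat <- c("forest", "non_forest_vegetation", "grassland")
  rel <- relocate_excess(area[, "cropland"], potential_ha, cap, protected,
                         receiver_capacity = rowSums(area[, nat, drop = FALSE]))
  area[, "cropland"] <- area[, "cropland"] - rel$removed + rel$received
  area[, restore_class] <- area[, restore_class] + rel$removed
  pos <- rel$received > 0
  if (any(pos)) {
    w <- state$area[pos, nat, drop = FALSE] /
      rowSums(state$area[pos, nat, drop = FALSE])
    area[pos, nat] <- area[pos, nat] - rel$received[pos] * w
  }
  plan <- data.frame(cell = seq_len(nrow(area)), removed_ha = rel$removed,
                     received_ha = rel$received)
  attr(plan, "total_moved") <- sum(rel$removed)
  list(state = coarse_state(area, state$spec, state$legend), plan = plan)
}
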