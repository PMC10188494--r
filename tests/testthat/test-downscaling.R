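test_that("terrain roughness index: flat, spike and translation invariance", {
  spec <- make_spec(n = 20, f = 10)
  flat <- continuous_raster(matrix(5, 20, 20), spec, "m")
  expect_true(all(compute_tri(flat)$values == 0))
  z <- matrix(0, 20, 20)
  z[10, 10] <- 1
  tri <- compute_tri(continuous_raster(z, spec, "m"))
  expect_equal(tri$values[10, 10], sqrt(8))  # 8 neighbours each differ by 1
  expect_equal(tri$values[9, 9], 1)          # one neighbour differs by 1
  expect_equal(tri$values[5, 5], 0)
  shifted <- compute_tri(continuous_raster(z + 100, spec, "m"))
  expect_equal(shifted$values, tri$values)
})

test_that("adjacency surfaces: saturation, absence, single-source kernel", {
  spec <- make_spec(n = 41, f = 41)
  p <- alloc_params(w_near = 0.7, w_far = 0.2, sigma_near = 2, sigma_far = 5)
  allc <- uniform_lc("cropland", spec)
  a <- adjacency_surface(allc, "cropland", p)
  expect_equal(a$values, matrix(0.9, 41, 41), tolerance = 1e-12)
  expect_true(all(adjacency_surface(allc, "forest", p)$values == 0))
  # single class pixel at the centre: origin value from an independent
  # evaluation of the two truncated-Gaussian kernels
  one <- uniform_lc("forest", spec)
  one$values[21, 21] <- default_legend()["cropland"]
  a1 <- adjacency_surface(one, "cropland", p)
  expect_equal(a1$values[21, 21],
               0.7 * kernel_origin_value(2) + 0.2 * kernel_origin_value(5),
               tolerance = 1e-12)
  expect_error(alloc_params(sigma_near = 5, sigma_far = 2), "sigma_near")
})

test_that("physical suitability combines min-max normalised SOC and TRI", {
  spec <- grid_spec(n_rows = 2, n_cols = 2, coarse_factor = 2)
  soc <- continuous_raster(matrix(c(10, 20, 30, 40), 2, 2), spec, "t C ha-1")
  tri <- continuous_raster(matrix(c(0, 1, 2, 4), 2, 2), spec, "m")
  p <- alloc_params(a_soc = 0.6, b_tri = 0.4)
  s <- physical_suitability(soc, tri, "cropland", p)
  # hand evaluation of the min-max combination
  soc01 <- (c(10, 20, 30, 40) - 10) / 30
  tri01 <- c(0, 1, 2, 4) / 4
  expect_equal(as.vector(s$values), 0.6 * soc01 + 0.4 * (1 - tri01))
  # zero weights -> zero surface; constant inputs -> the 0.5 convention
  expect_true(all(physical_suitability(soc, tri, "cropland",
                                       alloc_params(a_soc = 0, b_tri = 0))$values == 0))
  const <- continuous_raster(matrix(7, 2, 2), spec, "")
  s2 <- physical_suitability(const, const, "cropland",
                             alloc_params(a_soc = 1, b_tri = 1))
  expect_equal(s2$values, matrix(1, 2, 2))
})

test_that("eligibility: terminal classes, default matrix, protection rules", {
  spec <- make_spec(n = 4, f = 2)
  water <- uniform_lc("water", spec)
  elig <- build_eligibility(water)
  for (g in names(default_legend()))
    expect_false(any(target_mask(elig, water, g)))
  leg <- default_legend()
  lc <- uniform_lc("forest", spec)
  lc$values[1, 1] <- leg["urban"]
  e2 <- build_eligibility(lc)
  m <- target_mask(e2, lc, "cropland")
  expect_false(m[1, 1])          # urban never converts
  expect_true(m[2, 2])           # forest -> cropland allowed by default
  prot <- matrix(FALSE, 4, 4)
  prot[2, 2] <- TRUE
  e3 <- build_eligibility(lc, prot)
  expect_false(target_mask(e3, lc, "cropland")[2, 2])  # protected natural source
  # protected cropland may still be restored to natural classes
  lc2 <- uniform_lc("cropland", spec)
  e4 <- build_eligibility(lc2, prot)
  expect_true(target_mask(e4, lc2, "forest")[2, 2])
  expect_false(target_mask(e4, lc2, "urban")[2, 2])
})

test_that("allocation: identity, ranked choice, conservation, determinism", {
  leg <- default_legend()
  model <- cell_area_model(uniform_area = 1)
  # 1 coarse cell of 2x2 pixels: +1 cropland / -1 forest, scores decide
  spec1 <- grid_spec(n_rows = 2, n_cols = 2, coarse_factor = 2)
  lc <- categorical_raster(matrix(leg[c("forest", "cropland",
                                        "forest", "grassland")],
                                  2, 2, byrow = TRUE), spec1)
  delta <- matrix(0, 1, 7, dimnames = list(NULL, names(leg)))
  delta[1, "cropland"] <- 1
  delta[1, "forest"] <- -1
  ch <- coarse_changes(delta, spec1)
  stack <- lapply(stats::setNames(names(leg), names(leg)),
                  function(g) matrix(0, 2, 2))
  stack$cropland <- matrix(c(0.9, 0.2, 0, 0), 2, 2)  # forest pixels 0.9, 0.2
  elig <- build_eligibility(lc)
  res <- allocate_changes(lc, ch, stack, elig, model)
  expect_equal(nrow(res$report), 1)
  expect_equal(res$report$from, "forest")
  expect_equal(res$report$score, 0.9)
  expect_equal(res$lc$values[1, 1], unname(leg["cropland"]))  # the 0.9 pixel
  # zero change -> identical map, empty report
  zero <- coarse_changes(delta * 0, spec1)
  r0 <- allocate_changes(lc, zero, stack, elig, model)
  expect_identical(r0$lc$values, lc$values)
  expect_equal(nrow(r0$report), 0)
  # raising a winning pixel's score keeps it in the converted set
  stack2 <- stack
  stack2$cropland[1, 1] <- 2.5
  r2 <- allocate_changes(lc, ch, stack2, elig, model)
  expect_equal(r2$lc$values[1, 1], unname(leg["cropland"]))
  # seeded synthetic scenario: aggregation equals the rounded change set
  spec <- make_spec(n = 60, f = 20)
  lcs <- gen_landscape(landscape_gen_config(seed = 51, spec = spec))
  st <- aggregate_to_coarse(lcs, cell_area_model(uniform_area = 9))
  covs <- gen_covariates(52, spec)
  chs <- gen_coarse_scenario(st, covs, scenario_preset("BAU"),
                             scenario_demand_config(seed = 5))
  e <- build_eligibility(lcs)
  stk <- suitability_stack(lcs, covs$soc, compute_tri(covs$dem),
                           alloc_params(), e)
  out <- allocate_changes(lcs, chs[[1]], stk, e,
                          cell_area_model(uniform_area = 9))
  st1 <- aggregate_to_coarse(out$lc, cell_area_model(uniform_area = 9))
  tgt <- matrix(out$targets$target_px, ncol = 7, byrow = TRUE)
  expect_equal((st1$area - st$area) / 9, tgt, ignore_attr = TRUE)
  out2 <- allocate_changes(lcs, chs[[1]], stk, e,
                           cell_area_model(uniform_area = 9))
  expect_identical(out$lc$values, out2$lc$values)
  # infeasible demand errors with per-cell deficits, never partial output
  bad <- delta
  bad[1, "cropland"] <- 3
  bad[1, "forest"] <- -3
  expect_error(allocate_changes(lc, coarse_changes(bad, spec1), stack, elig,
                                model),
               class = "landshift_infeasible")
})

test_that("allocation loss counts mismatched change", {
  spec <- make_spec(n = 4, f = 2)
  base <- uniform_lc("forest", spec)
  obs <- base
  obs$values[1, 1:3] <- default_legend()["cropland"]
  expect_equal(allocation_loss(obs, obs, base), 0)
  expect_equal(allocation_loss(base, obs, base), 1)
  pred <- base
  pred$values[1, 1:2] <- default_legend()["cropland"]
  pred$values[2, 1] <- default_legend()["cropland"]
  # union of changed pixels = {[1,1],[1,2],[1,3],[2,1]} (4); mismatches:
  # [1,3] missed and [2,1] spurious -> 2/4
  expect_equal(allocation_loss(pred, obs, base), 0.5)
  expect_equal(allocation_loss(base, base, base), 0)
})

test_that("calibration returns the loss-minimising candidate deterministically", {
  spec <- make_spec(n = 40, f = 20)
  lc <- gen_landscape(landscape_gen_config(seed = 61, spec = spec))
  st <- aggregate_to_coarse(lc)
  covs <- gen_covariates(62, spec)
  ch <- gen_coarse_scenario(st, covs, scenario_preset("BAU"),
                            scenario_demand_config(
                              years = seq(2015, 2035, 5), seed = 6))
  truth <- alloc_params(w_near = 1, w_far = 0.3, sigma_near = 2,
                        sigma_far = 8)
  obs <- gen_history(truth, lc, ch, covs)
  fit_n <- 2
  cands <- list(alloc_params(w_near = 0.1, w_far = 1.5, sigma_near = 1.1,
                             sigma_far = 12),
                truth,
                alloc_params(w_near = 2, w_far = 0, sigma_near = 4,
                             sigma_far = 16, a_soc = 2, b_tri = 0))
  fit <- calibrate_allocation(cands, lc, ch[seq_len(fit_n)], obs[seq_len(fit_n)],
                              ch[-seq_len(fit_n)], obs[-seq_len(fit_n)], covs)
  expect_equal(fit$index, 2)
  expect_equal(fit$loss, 0)
  expect_true(all(fit$losses >= fit$loss))
  # single candidate is returned as-is; equal losses break to the first
  single <- calibrate_allocation(cands[2], lc, ch[1:2], obs[1:2],
                                 ch[3:4], obs[3:4], covs)
  expect_identical(single$params, truth)
  tie <- calibrate_allocation(list(truth, truth), lc, ch[1:2], obs[1:2],
                              ch[3:4], obs[3:4], covs)
  expect_equal(tie$index, 1)
  expect_error(calibrate_allocation(list(), lc, ch[1:2], obs[1:2],
                                    ch[3:4], obs[3:4], covs), "empty")
})
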