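test_that("driver contrast: identical maps give null results, Bonferroni math", {
  cfg <- synthetic_config(seed = 60, grid_shape = c(30, 30), n_records = 120)
  tr <- generate_records(cfg)
  suit <- tr$true_suitability$non_melanistic
  g <- tr$env$grid
  full <- scale_definition("full", extent = c(g$xmin, 99, g$ymin, 99))
  half <- scale_definition("half", extent = c(g$xmin, g$xmin + 0.75, g$ymin, 99))
  dc <- driver_contrast(tr$records, tr$env, suit, suit, list(full, half),
                        alpha = 0.05)
  expect_true(all(abs(dc$contrasts$t) < 1e-9))
  expect_true(all(!dc$contrasts$significant))
  # threshold = alpha / (variables x scales)
  expect_equal(dc$threshold, 0.05 / (3 * 2))
  expect_equal(dc$n_tests, 6)
  # per-phenotype regressions present for both models
  expect_true(all(c("slope_minor", "R_major") %in% names(dc$regressions)))
  expect_equal(dc$regressions$slope_minor, dc$regressions$slope_major)
})

test_that("driver contrast recovers a directional moisture association", {
  # melanistic niche loads on moisture; non-melanistic flat
  cfg <- synthetic_config(seed = 61, grid_shape = c(40, 40), n_records = 500,
                          n_melanistic = 100,
                          niche_coeffs = list(
                            population = list(linear = c(0, 0.3, 0)),
                            melanistic = list(linear = c(2.5, 0, 0))))
  tr <- generate_records(cfg)
  g <- tr$env$grid
  full <- scale_definition("full", extent = c(g$xmin, 99, g$ymin, 99))
  suit_mel <- tr$true_suitability$melanistic
  suit_nm <- tr$true_suitability$non_melanistic
  dc <- driver_contrast(tr$records, tr$env, suit_mel, suit_nm, list(full))
  reg <- dc$regressions[dc$regressions$variable == "moisture", ]
  expect_gt(reg$slope_minor, reg$slope_major)
  expect_gt(reg$R_minor, reg$R_major + 0.1)
  moist <- dc$contrasts[dc$contrasts$variable == "moisture", ]
  expect_gt(moist$mean_minor, moist$mean_major)
  expect_true(moist$significant)
})

test_that("barrier contrast: constructed step detected with correct sign", {
  cfg <- synthetic_config(seed = 62, grid_shape = c(60, 60), n_records = 2,
                          barrier_step = 1.0)
  tr <- generate_records(cfg)
  by <- tr$env$grid$ymin +
    (tr$env$grid$nrow - cfg$barrier_row) * tr$env$grid$cellsize
  br <- barrier_contrast(tr$env, by, tr$biomes, biome_class = 4,
                         n_points = 600, seed = 3)
  expect_lt(br$p, 0.001)
  expect_gt(br$mean_south, br$mean_north)
  expect_gt(br$t, 0)
  # exchangeability: swapping sides flips t exactly
  t_flip <- t.test(br$values_north, br$values_south)$statistic
  expect_equal(unname(t_flip), -br$t, tolerance = 1e-12)
  expect_error(barrier_contrast(tr$env, by, tr$biomes, 4, n_points = 601),
               "even")
  expect_error(barrier_contrast(tr$env, by, tr$biomes, 4, n_points = 6000),
               "insufficient")
})

test_that("barrier contrast size is calibrated on independent-noise worlds", {
  # reduced-scale (acceptance runs 200 trials); iid moisture -> t-test valid
  rej <- vapply(1:40, function(i) {
    cfg <- synthetic_config(seed = 7000 + i, grid_shape = c(40, 40),
                            n_records = 2, autocorr_range = 0)
    tr <- generate_records(cfg)
    by <- tr$env$grid$ymin +
      (tr$env$grid$nrow - cfg$barrier_row) * tr$env$grid$cellsize
    br <- barrier_contrast(tr$env, by, tr$biomes, 4, n_points = 100,
                           seed = i)
    br$p <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("leave_region_out: identity, robustness and error contracts", {
  cfg <- strong_niche_config(seed = 63, n_records = 200, grid = c(40, 40))
  tr <- generate_records(cfg)
  rec <- tr$records
  proto <- maxent_protocol(n_background = 800)
  # disjoint region: bit-identical refit under the same seed
  empty <- scale_definition("none", extent = c(50, 51, 50, 51))
  lro0 <- leave_region_out(rec, tr$env, empty, proto, seed = 2)
  expect_identical(lro0$map_full, lro0$map_loro)
  expect_equal(lro0$n_excluded, 0)
  # hotspot region whose signal is shared with retained records
  hot <- which(tr$true_suitability$non_melanistic >
                 quantile(tr$true_suitability$non_melanistic, 0.9,
                          na.rm = TRUE), arr.ind = TRUE)
  cc <- cell_centers(tr$env$grid)
  hx <- cc$x[(hot[1, 2] - 1) * 40 + hot[1, 1]]
  hy <- cc$y[(hot[1, 2] - 1) * 40 + hot[1, 1]]
  region <- scale_definition("hot", extent = c(hx - 0.2, hx + 0.2,
                                               hy - 0.2, hy + 0.2))
  lro <- leave_region_out(rec, tr$env, region, proto, seed = 2)
  expect_gte(lro$region_mean_after, 0.8 * lro$region_mean_before)
  # region covering everything -> error
  all_reg <- scale_definition("all", extent = c(-10, 99, -10, 99))
  expect_error(leave_region_out(rec, tr$env, all_reg, proto), "every")
})
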