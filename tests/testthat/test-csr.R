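test_that("study polygon: buffer discs merge and area tracks geometry", {
  one <- build_study_polygon(data.frame(lon = 10, lat = 5), buffer_km = 200)
  expect_equal(one$area_km2, pi * 200^2, tolerance = 0.01)
  # two points 500 km apart: two disjoint discs
  two <- build_study_polygon(
    data.frame(lon = c(0, 500 / 111.32), lat = c(0, 0)), buffer_km = 200)
  expect_equal(two$area_km2, 2 * pi * 200^2, tolerance = 0.01)
  # 100 km apart: a single connected blob, area < 2 discs
  near <- build_study_polygon(
    data.frame(lon = c(0, 100 / 111.32), lat = c(0, 0)), buffer_km = 200)
  expect_lt(near$area_km2, 2 * pi * 200^2 * 0.95)
  expect_gt(near$area_km2, pi * 200^2)
  # every point lies inside the mask
  set.seed(2)
  rec <- data.frame(lon = runif(20, 0, 4), lat = runif(20, 0, 4))
  poly <- build_study_polygon(rec, buffer_km = 150)
  pts <- melaniche:::polygon_points(rec, poly)
  idx <- cell_from_xy(poly$grid, pts$x, pts$y)
  expect_true(all(poly$mask[idx]))
})

test_that("kernel intensity integrates to n and is flat for uniform points", {
  gridpts <- expand.grid(lon = seq(0, 2, length.out = 12),
                         lat = seq(0, 2, length.out = 12))
  poly <- build_study_polygon(gridpts, buffer_km = 80)
  ki <- fit_kernel_intensity(gridpts, poly)
  expect_equal(sum(ki$values, na.rm = TRUE) * ki$grid$cellsize^2,
               nrow(gridpts), tolerance = 1e-9)
  # near-constant intensity over the core (inside the point bounding box,
  # away from the buffer fringe where any kernel estimate decays)
  pts <- melaniche:::polygon_points(gridpts, poly)
  cc <- cell_centers(ki$grid)
  core <- !is.na(as.vector(ki$values)) &
    cc$x > min(pts$x) & cc$x < max(pts$x) &
    cc$y > min(pts$y) & cc$y < max(pts$y)
  v <- as.vector(ki$values)[core]
  expect_lt(sd(v) / mean(v), 0.2)
  # tight cluster: maximum at the cluster centre cell
  clus <- data.frame(lon = 1 + rnorm(30, 0, 0.01), lat = 1 + rnorm(30, 0, 0.01))
  poly2 <- build_study_polygon(clus, buffer_km = 100)
  ki2 <- fit_kernel_intensity(clus, poly2)
  peak <- which(ki2$values == max(ki2$values, na.rm = TRUE), arr.ind = TRUE)
  cc <- cell_centers(ki2$grid)
  peak_idx <- (peak[1, 2] - 1) * ki2$grid$nrow + peak[1, 1]
  ctr <- melaniche:::polygon_points(data.frame(lon = 1, lat = 1), poly2)
  expect_lt(sqrt((cc$x[peak_idx] - ctr$x)^2 + (cc$y[peak_idx] - ctr$y)^2),
            3 * ki2$grid$cellsize)
  expect_error(fit_kernel_intensity(data.frame(lon = c(1, 1), lat = c(2, 2)),
                                    poly2), "identical")
})

test_that("G-function is a nondecreasing step function from 0 to 1", {
  set.seed(4)
  x <- runif(40); y <- runif(40)
  r <- seq(0, 2, length.out = 256)
  g <- g_function(x, y, r)
  expect_true(all(diff(g) >= 0))
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 1)
})

test_that("csr_test contracts: p bounds, envelope, input validation", {
  set.seed(5)
  rec <- data.frame(lon = runif(40, 0, 2), lat = runif(40, 0, 2))
  poly <- build_study_polygon(rec, buffer_km = 100)
  res <- csr_test(rec, poly, n_sim = 39, seed = 3)
  expect_gte(res$p_value, 1 / 40)
  expect_lte(res$p_value, 1)
  expect_true(all(res$g_null_envelope[, "low"] <= res$g_null_mean + 1e-12))
  expect_true(all(res$g_null_envelope[, "high"] >= res$g_null_mean - 1e-12))
  expect_error(csr_test(rec[1:2, ], poly, n_sim = 39), "at least 3")
  expect_error(csr_test(rec, poly, n_sim = 10), ">= 39")
})

test_that("size: self-simulated patterns are rejected at about alpha", {
  # reduced-scale calibration (acceptance runs the full 200-trial version)
  set.seed(90)
  base <- data.frame(lon = runif(50, 0, 2.5), lat = runif(50, 0, 2.5))
  poly <- build_study_polygon(base, buffer_km = 100, target_cells = 100)
  ki <- fit_kernel_intensity(base, poly)
  rej <- vapply(1:60, function(i) {
    set.seed(400 + i)
    obs <- simulate_from_intensity(ki, 50)
    csr_test(obs, poly, n_sim = 39, seed = 800 + i, intensity = ki)$p_value <= 0.05
  }, logical(1))
  ci <- binom.test(sum(rej), length(rej), p = 0.05)$conf.int
  expect_true(0.05 >= ci[1] && 0.05 <= ci[2])
})

test_that("power: clustered patterns under a broad kernel are detected", {
  set.seed(91)
  base <- data.frame(lon = runif(60, 0, 3), lat = runif(60, 0, 3))
  poly <- build_study_polygon(base, buffer_km = 120, target_cells = 100)
  ki <- fit_kernel_intensity(base, poly)
  ps <- vapply(1:5, function(i) {
    set.seed(70 + i)
    clus <- data.frame(lon = rnorm(35, 1.5, 0.07), lat = rnorm(35, 1.5, 0.07))
    csr_test(clus, poly, n_sim = 99, seed = i, intensity = ki)$p_value
  }, numeric(1))
  expect_true(all(ps <= 0.05))
})
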