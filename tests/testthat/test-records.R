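test_that("read_records validates and flags unconfirmed phenotypes", {
  rec <- make_records(8)
  rec$phenotype[1:2] <- "melanistic"
  rec$phenotype[3] <- "unconfirmed_melanistic"
  out <- read_records(rec)
  expect_equal(sum(out$eligible), 7)
  expect_equal(nrow(modelling_records(out)), 7)
  # the published tally: 624 records, 5 unconfirmed -> 619 modelling-eligible
  big <- make_records(624, seed = 2)
  big$phenotype[1:67] <- "melanistic"
  big$phenotype[68:72] <- "unconfirmed_melanistic"
  expect_equal(nrow(modelling_records(read_records(big))), 619)
})

test_that("read_records errors name the offending rows/labels", {
  rec <- make_records(4)
  rec$lat[3] <- 95
  expect_error(read_records(rec), "row\\(s\\): 3")
  rec2 <- make_records(4)
  rec2$phenotype[2] <- "blackish"
  expect_error(read_records(rec2), "blackish")
  expect_warning(out <- read_records(make_records(0)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("camera-trap dedup collapses nearby same-phenotype records only", {
  km10 <- 10 / 111.19   # ~10 km in degrees of latitude
  rec <- read_records(data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    lon = c(0, 0, 0, 0, 2, 2),
    lat = c(0, km10, 30 / 111.19 * 3, 0.001, 0, km10),
    phenotype = c("non_melanistic", "non_melanistic", "non_melanistic",
                  "melanistic", "non_melanistic", "non_melanistic"),
    source = c("camera_trap", "camera_trap", "camera_trap", "camera_trap",
               "museum", "camera_trap"),
    year = 2010L))
  out <- dedup_camera_traps(rec, diameter_km = 25)
  # b collapses into a (10 km, same phenotype); c kept (>25 km);
  # d kept (different phenotype); e museum untouched; f kept (near e only)
  expect_setequal(out$id, c("a", "c", "d", "e", "f"))
  # brute-force invariant: no removed record was >= 25 km from every keeper
  removed <- setdiff(rec$id, out$id)
  for (rid in removed) {
    i <- which(rec$id == rid)
    d <- haversine_km(rec$lon[i], rec$lat[i], out$lon, out$lat)
    expect_true(any(d < 25))
  }
  # identified individuals are never merged
  rec$individual_id <- c("L1", "L2", "", "", "", "")
  expect_equal(nrow(dedup_camera_traps(rec, 25)), 6)
})

test_that("filter_records applies age, duplicate and NDVI rules in order", {
  fx <- filtering_fixture()
  res <- filter_records(fx$records, reference_year = 2013,
                        ndvi_change = fx$ndvi, ndvi_grid = fx$grid)
  expect_equal(res$report$n_input, 619)
  expect_equal(res$report$n_removed_age, 10)
  expect_equal(res$report$n_removed_duplicate, 12)
  expect_equal(res$report$n_removed_ndvi, 12)
  expect_equal(res$report$n_output, 585)
  expect_equal(nrow(res$records), 585)
  expect_equal(length(res$report$removed_ids), 34)
  # idempotence
  res2 <- filter_records(res$records, 2013, fx$ndvi, fx$grid)
  expect_equal(res2$report$n_output, 585)
  expect_equal(sum(res2$report$n_removed_age, res2$report$n_removed_duplicate,
                   res2$report$n_removed_ndvi), 0)
  # report serialises
  j <- jsonlite::fromJSON(filter_report_json(res$report))
  expect_equal(j$n_output, 585)
})

test_that("filter edge cases: clean inputs, exact duplicates, off-grid", {
  rec <- make_records(10, seed = 4)
  res <- filter_records(rec, 2013)
  expect_equal(res$report$n_output, 10)
  rec2 <- rbind(rec, rec[3, ])
  rec2$id[11] <- "R999"
  res2 <- filter_records(rec2, 2013)
  expect_equal(res2$report$n_removed_duplicate, 1)
  # duplicate with conflicting phenotypes keeps the melanistic record
  rec3 <- rec[c(1, 1), ]; rec3$id <- c("x", "y")
  rec3$phenotype[2] <- "melanistic"
  expect_warning(res3 <- filter_records(rec3, 2013), "melanistic")
  expect_equal(res3$records$id, "y")
  # record outside the NDVI raster is kept, with a warning
  grid <- env_grid(5, 5, 0, 0, 0.1)
  ndvi <- matrix(0, 5, 5)
  rec4 <- make_records(2, seed = 5)
  rec4$lon[2] <- 50
  expect_warning(res4 <- filter_records(rec4, 2013, ndvi, grid), "outside")
  expect_equal(res4$report$n_output, 2)
})

test_that("assign_biomes labels from the raster and warns off-grid", {
  cfg <- synthetic_config(seed = 3, grid_shape = c(20, 20), n_records = 50)
  tr <- generate_records(cfg)
  rec <- tr$records
  rec$biome <- NULL
  out <- assign_biomes(rec, tr$biomes, tr$env$grid, tr$biome_levels)
  expect_identical(out$biome, tr$records$biome)  # matches generating raster
  off <- rec[1, ]; off$lon <- 99
  expect_warning(out2 <- assign_biomes(off, tr$biomes, tr$env$grid),
                 "no biome")
  expect_true(is.na(out2$biome))
})
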