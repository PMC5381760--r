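# Shared fixtures, built in code.

# The published biome-by-phenotype counts (11 biomes x 2 phenotypes).
table1_counts <- function() {
  matrix(c(69, 13, 2, 47, 108, 5, 2, 5, 38, 126, 137,
           0, 0, 0, 3, 3, 0, 0, 0, 2, 0, 59),
         ncol = 2,
         dimnames = list(c("desert_xeric", "mediterranean", "tundra",
                           "montane_grassland", "temperate_broadleaf",
                           "temperate_conifer", "temperate_grassland",
                           "tropical_conifer", "tropical_dry_broadleaf",
                           "tropical_grassland", "tropical_moist_broadleaf"),
                         c("non_melanistic", "melanistic")))
}

# tiny aligned env stack on an n x n grid with deterministic layers
tiny_env <- function(n = 10, seed = 1) {
  set.seed(seed)
  grid <- env_grid(n, n, xmin = 0, ymin = 0, cellsize = 0.1)
  env_stack(list(a = matrix(rnorm(n * n), n, n),
                 b = matrix(rnorm(n * n), n, n)), grid)
}

# valid record table for records_io tests
make_records <- function(n = 10, seed = 1, source = "field_capture") {
  set.seed(seed)
  data.frame(id = sprintf("R%03d", seq_len(n)),
             lon = runif(n, 0, 1), lat = runif(n, 0, 1),
             phenotype = rep("non_melanistic", n),
             source = rep(source, n), year = rep(2010L, n),
             stringsAsFactors = FALSE)
}

# independent chi-square / G oracle: cell-by-cell double loop
oracle_chisq <- function(counts) {
  n <- sum(counts); chi <- 0; g <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    e <- sum(counts[i, ]) * sum(counts[, j]) / n
    chi <- chi + (counts[i, j] - e)^2 / e
    if (counts[i, j] > 0) g <- g + 2 * counts[i, j] * log(counts[i, j] / e)
  }
  list(chi = as.numeric(chi), g = as.numeric(g))
}

# independent RR oracle: explicit pair loop on two vectors
oracle_rr <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  agree <- 0; total <- 0
  for (i in seq_len(length(p) - 1)) for (j in seq(i + 1, length(p))) {
    sp <- sign(p[i] - p[j]); sq <- sign(q[i] - q[j])
    agree <- agree + (sp == sq || sp == 0 || sq == 0)
    total <- total + 1
  }
  agree / total
}

# synthetic world used by the heavier power checks: strong, concentrated niche
strong_niche_config <- function(seed, n_records = 300, grid = c(60, 60)) {
  synthetic_config(seed = seed, grid_shape = grid, n_records = n_records,
                   niche_coeffs = list(population = list(
                     linear = c(3, 1.5, 0), quadratic = c(-2, -2, 0))))
}

# criterion-7 world: 619 records of which exactly 34 violate one filter rule
# (10 too old, 12 exact-duplicate extras, 12 on high-NDVI-change cells)
filtering_fixture <- function(seed = 42) {
  set.seed(seed)
  n_grid <- 30
  grid <- env_grid(n_grid, n_grid, xmin = 0, ymin = 0, cellsize = 0.1)
  ndvi <- matrix(runif(n_grid^2, -0.5, 0.5), n_grid, n_grid)
  bad_cells <- c(5, 50, 123)          # cells pushed past the 0.7 cutoff
  ndvi[bad_cells] <- 0.9
  cc <- cell_centers(grid)
  clean_cells <- setdiff(seq_len(n_grid^2), bad_cells)
  base_n <- 619 - 10 - 12 - 12        # records passing every rule
  cells <- sample(clean_cells, base_n + 10, replace = TRUE)
  jit <- function(k) runif(k, -0.03, 0.03)
  rec <- data.frame(
    id = sprintf("F%04d", seq_along(cells)),
    lon = cc$x[cells] + jit(length(cells)),
    lat = cc$y[cells] + jit(length(cells)),
    phenotype = sample(c("non_melanistic", "melanistic"),
                       length(cells), TRUE, prob = c(0.9, 0.1)),
    source = "field_capture",
    year = 2010L, stringsAsFactors = FALSE)
  rec$year[seq_len(10)] <- 1985L      # 10 age violations (ref year 2013)
  dup_src <- seq(11, 22)              # 12 duplicate extras of clean records
  dups <- rec[dup_src, ]
  dups$id <- sprintf("D%04d", seq_len(12))
  dups$year <- 2010L
  dups$phenotype <- rec$phenotype[dup_src]  # same phenotype: no conflict
  ndvi_idx <- sample(bad_cells, 12, replace = TRUE)
  ndvi_rec <- data.frame(
    id = sprintf("N%04d", seq_len(12)),
    lon = cc$x[ndvi_idx] + jit(12), lat = cc$y[ndvi_idx] + jit(12),
    phenotype = "non_melanistic", source = "field_capture",
    year = 2010L, stringsAsFactors = FALSE)
  records <- rbind(rec, dups, ndvi_rec)
  stopifnot(nrow(records) == 619)
  list(records = records, ndvi = ndvi, grid = grid)
}
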