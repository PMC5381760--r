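#' Configuration for a synthetic landscape with known niche structure
#'
#' The generator stands in for range-wide occurrence data plus gridded
#' environmental layers: correlated, spatially autocorrelated continuous
#' gradients; a categorical biome map correlated with the first gradient; a
#' landscape-change (NDVI delta) layer; and phenotype-labelled presence
#' records whose locations follow a known suitability surface and whose
#' melanism labels follow per-biome frequencies.
#'
#' Defaults encode the stated study world: ~600 records, ~10% melanistic
#' overall, melanism concentrated in the wettest biome (frequency 0.30 there,
#' near zero in open/dry classes), 3 environmental gradients, 4 biomes.
#'
#' @param grid_shape integer c(rows, cols).
#' @param cell_size cell edge in degrees.
#' @param origin c(xmin, ymin) of the grid in degrees.
#' @param n_layers number of continuous environmental layers.
#' @param layer_names names for the layers.
#' @param target_corr desired pairwise correlation matrix among layers
#'   (symmetric positive semi-definite).
#' @param autocorr_range Gaussian smoothing length in cells (0 = white noise).
#' @param n_biomes number of biome classes (class `n_biomes` is the wettest).
#' @param biome_props optional class area proportions (default equal).
#' @param n_records total individuals to sample.
#' @param melanism_freq_by_biome per-biome probability of melanism, length
#'   `n_biomes`, ordered dry to wet.
#' @param niche_coeffs list of per-phenotype coefficient lists
#'   `list(linear=, quadratic=)` on the standardised layers. Entry
#'   `population` drives where individuals occur; an optional `melanistic`
#'   entry switches the generator to per-phenotype location sampling (used
#'   for niche-difference power experiments) together with `n_melanistic`.
#' @param n_melanistic melanistic count when `niche_coeffs$melanistic` is set.
#' @param barrier_row grid row acting as a geographic barrier for the
#'   moisture-contrast test; a moisture step of `barrier_step` is added south
#'   of it when nonzero.
#' @param barrier_step moisture offset added south of the barrier (default 0).
#' @param seed RNG seed.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(grid_shape = c(100, 100),
                             cell_size = 0.05,
                             origin = c(0, 0),
                             n_layers = 3,
                             layer_names = NULL,
                             target_corr = NULL,
                             autocorr_range = 5,
                             n_biomes = 4,
                             biome_props = NULL,
                             n_records = 600,
                             melanism_freq_by_biome = c(0.0, 0.02, 0.06, 0.30),
                             niche_coeffs = NULL,
                             n_melanistic = NULL,
                             barrier_row = NULL,
                             barrier_step = 0,
                             seed = 1L) {
  if (is.null(layer_names))
    layer_names <- c("moisture", "temperature", "elevation",
                     paste0("env", seq_len(max(0, n_layers - 3))))[seq_len(n_layers)]
  if (is.null(target_corr)) {
    target_corr <- diag(n_layers)
    if (n_layers >= 2) target_corr[1, 2] <- target_corr[2, 1] <- 0.5
  }
  if (is.null(niche_coeffs))
    niche_coeffs <- list(population = list(
      linear = c(0.4, 0.3, rep(0, n_layers - 2)),
      quadratic = c(-0.3, -0.3, rep(0, n_layers - 2))))
  if (is.null(barrier_row)) barrier_row <- floor(grid_shape[1] / 2)
  cfg <- structure(
    list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
         origin = origin, n_layers = as.integer(n_layers),
         layer_names = layer_names, target_corr = target_corr,
         autocorr_range = autocorr_range, n_biomes = as.integer(n_biomes),
         biome_props = biome_props, n_records = as.integer(n_records),
         melanism_freq_by_biome = melanism_freq_by_biome,
         niche_coeffs = niche_coeffs, n_melanistic = n_melanistic,
         barrier_row = as.integer(barrier_row), barrier_step = barrier_step,
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  tc <- cfg$target_corr
  if (!isTRUE(all.equal(tc, t(tc), tolerance = 1e-10)))
    stop("target_corr must be symmetric")
  ev <- eigen(tc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_corr must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  if (nrow(tc) != cfg$n_layers)
    stop("target_corr dimension must equal n_layers")
  if (any(cfg$melanism_freq_by_biome < 0 | cfg$melanism_freq_by_biome > 1))
    stop("melanism_freq_by_biome values must lie in [0, 1]")
  if (length(cfg$melanism_freq_by_biome) != cfg$n_biomes)
    stop("melanism_freq_by_biome must have one entry per biome")
  if (cfg$n_records < 2) stop("n_records must be >= 2")
  invisible(cfg)
}

# Periodic Gaussian smoothing of a matrix via FFT; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  gk <- function(n) {
    d <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    exp(-d^2 / (2 * sigma^2))
  }
  k <- outer(gk(nr), gk(nc))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (nr * nc)
}

# One standardised smoothed Gaussian random field as a vector over cells.
smooth_field <- function(nr, nc, sigma) {
  f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma)
  as.vector(scale(as.vector(f)))
}

#' Generate the continuous environmental layers
#'
#' Builds `n_layers` spatially autocorrelated random fields whose empirical
#' pairwise correlation over valid cells equals `target_corr` (smoothed white
#' noise, empirically orthogonalised, then mixed through the Cholesky factor
#' of the target matrix — so the realised correlations match the target to
#' numerical precision, not merely in expectation).
#'
#' @param cfg a `synthetic_config`.
#' @return an `env_stack` with standardised (mean 0, sd 1) layers.
#' @export
generate_env_stack <- function(cfg) {
  validate_synthetic_config(cfg)
  set.seed(stage_seed(cfg$seed, "env_stack"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  L <- cfg$n_layers
  raw <- vapply(seq_len(L), function(i) smooth_field(nr, nc, cfg$autocorr_range),
                numeric(nr * nc))
  # empirical orthonormalisation, then impose the target correlation exactly
  q <- qr.Q(qr(scale(raw, scale = FALSE)))
  q <- scale(q)                      # unit-variance orthogonal columns
  mixed <- q %*% chol(cfg$target_corr)
  grid <- env_grid(nr, nc, cfg$origin[1], cfg$origin[2], cfg$cell_size)
  layers <- lapply(seq_len(L), function(i) matrix(mixed[, i], nr, nc))
  names(layers) <- cfg$layer_names
  if (cfg$barrier_step != 0 && "moisture" %in% names(layers)) {
    south <- seq(cfg$barrier_row + 1L, nr)   # rows below the barrier row
    layers$moisture[south, ] <- layers$moisture[south, ] + cfg$barrier_step
  }
  env_stack(layers, grid)
}

# log-suitability surface from coefficient list on standardised layers
niche_eta <- function(env, coeffs) {
  vals <- vapply(env$layers, as.vector, numeric(n_cells(env$grid)))
  lin <- coeffs$linear
  qd <- if (!is.null(coeffs$quadratic)) coeffs$quadratic else rep(0, ncol(vals))
  as.vector(vals %*% lin + (vals^2) %*% qd)
}

#' True suitability surface for a coefficient set
#'
#' `exp()` of a linear+quadratic form on the standardised layers, rescaled to
#' a maximum of 1 over valid cells.
#' @param env an `env_stack`.
#' @param coeffs list with `linear` and optional `quadratic` vectors.
#' @return matrix on the env grid.
#' @export
true_suitability_surface <- function(env, coeffs) {
  eta <- niche_eta(env, coeffs)
  s <- exp(eta - max(eta[as.vector(env$mask)]))
  s[!as.vector(env$mask)] <- NA
  matrix(s, env$grid$nrow, env$grid$ncol)
}

#' Generate biome raster, NDVI-change layer and phenotype-labelled records
#'
#' Locations are drawn with probability proportional to the population
#' suitability surface; each individual's phenotype is then Bernoulli with
#' the per-biome melanism frequency of its landing cell. When
#' `cfg$niche_coeffs$melanistic` is supplied (power experiments), melanistic
#' and non-melanistic locations are instead drawn from their own surfaces
#' with counts `n_melanistic` / `n_records - n_melanistic`.
#'
#' Records are placed at cell centres with a small uniform jitter so that
#' exact-duplicate filtering stays testable; sources and years mimic a
#' camera-trap-dominated modern database.
#'
#' @param cfg a `synthetic_config`.
#' @param env the `env_stack` from [generate_env_stack()] (regenerated from
#'   `cfg` when omitted).
#' @return a `synthetic_truth` object: `records` (data.frame), `env`,
#'   `biomes` (integer matrix), `biome_levels`, `true_suitability` (list of
#'   per-phenotype matrices), `ndvi_change` (matrix), `config`.
#' @export
generate_records <- function(cfg, env = NULL) {
  validate_synthetic_config(cfg)
  if (is.null(env)) env <- generate_env_stack(cfg)
  nr <- env$grid$nrow; nc <- env$grid$ncol
  maskv <- as.vector(env$mask)
  if (!any(maskv))
    stop("population suitability surface is all zero (no valid cells)")

  set.seed(stage_seed(cfg$seed, "biomes"))
  # biomes track the pre-barrier-step moisture: the barrier contrast emulates
  # a moisture difference across a barrier *within* one biome class
  m1 <- env$layers[[1]]
  if (cfg$barrier_step != 0 && names(env$layers)[1] == "moisture") {
    south <- seq(cfg$barrier_row + 1L, nr)
    m1[south, ] <- m1[south, ] - cfg$barrier_step
  }
  bf <- 0.75 * as.vector(m1) + 0.25 * smooth_field(nr, nc, cfg$autocorr_range)
  props <- cfg$biome_props
  if (is.null(props)) props <- rep(1 / cfg$n_biomes, cfg$n_biomes)
  qs <- quantile(bf[maskv], probs = cumsum(props)[-cfg$n_biomes])
  biomes <- matrix(findInterval(bf, c(-Inf, qs)), nr, nc)
  biomes[!env$mask] <- NA
  biome_levels <- paste0("biome_", seq_len(cfg$n_biomes))

  set.seed(stage_seed(cfg$seed, "ndvi"))
  ndvi_change <- matrix(0.35 * smooth_field(nr, nc, cfg$autocorr_range), nr, nc)
  ndvi_change[!env$mask] <- NA

  pop_s <- true_suitability_surface(env, cfg$niche_coeffs$population)
  sv <- as.vector(pop_s); sv[is.na(sv)] <- 0
  if (all(sv == 0)) stop("population suitability surface is all zero")

  set.seed(stage_seed(cfg$seed, "records"))
  per_phenotype <- !is.null(cfg$niche_coeffs$melanistic)
  if (per_phenotype) {
    n_mel <- cfg$n_melanistic
    if (is.null(n_mel)) n_mel <- max(2L, round(0.1 * cfg$n_records))
    mel_s <- true_suitability_surface(env, cfg$niche_coeffs$melanistic)
    mv <- as.vector(mel_s); mv[is.na(mv)] <- 0
    if (all(mv == 0)) stop("melanistic suitability surface is all zero")
    cells <- c(sample.int(nr * nc, cfg$n_records - n_mel, replace = TRUE, prob = sv),
               sample.int(nr * nc, n_mel, replace = TRUE, prob = mv))
    phen <- rep(c("non_melanistic", "melanistic"),
                c(cfg$n_records - n_mel, n_mel))
    truth_s <- list(non_melanistic = pop_s, melanistic = mel_s)
  } else {
    cells <- sample.int(nr * nc, cfg$n_records, replace = TRUE, prob = sv)
    pmel <- cfg$melanism_freq_by_biome[biomes[cells]]
    pmel[is.na(pmel)] <- 0
    phen <- ifelse(runif(cfg$n_records) < pmel, "melanistic", "non_melanistic")
    freq_surface <- matrix(cfg$melanism_freq_by_biome[biomes], nr, nc)
    mel_s <- pop_s * freq_surface
    if (any(mel_s > 0, na.rm = TRUE)) mel_s <- mel_s / max(mel_s, na.rm = TRUE)
    truth_s <- list(non_melanistic = pop_s, melanistic = mel_s)
  }

  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cs <- env$grid$cellsize
  lon <- env$grid$xmin + (col - 0.5) * cs + runif(length(cells), -0.35, 0.35) * cs
  lat <- env$grid$ymin + (nr - row + 0.5) * cs + runif(length(cells), -0.35, 0.35) * cs
  src <- sample(c("camera_trap", "museum", "field_capture", "communication"),
                length(cells), replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  year <- sample(2001:2013, length(cells), replace = TRUE)
  records <- data.frame(
    id = sprintf("REC%04d", seq_along(cells)),
    lon = lon, lat = lat, phenotype = phen, source = src, year = year,
    stringsAsFactors = FALSE)
  records$biome <- biome_levels[biomes[cells]]

  structure(list(records = records, env = env, biomes = biomes,
                 biome_levels = biome_levels, true_suitability = truth_s,
                 ndvi_change = ndvi_change, config = cfg),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  tab <- table(x$records$phenotype)
  cat(sprintf("<synthetic_truth> %d records (%s) on a %d x %d landscape, %d biomes\n",
              nrow(x$records),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$env$grid$nrow, x$env$grid$ncol, x$config$n_biomes))
  invisible(x)
}

#' Write a synthetic truth set to disk
#'
#' Records as CSV (`id, lon, lat, phenotype, source, year`), environmental
#' layers, biomes and NDVI change as ESRI ASCII grids.
#' @param truth a `synthetic_truth`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_synthetic_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$records[c("id", "lon", "lat", "phenotype", "source", "year")],
                   file.path(dir, "records.csv"), row.names = FALSE)
  write_env_stack(truth$env, file.path(dir, "env"))
  write_esri_ascii(truth$biomes, truth$env$grid, file.path(dir, "biomes.asc"),
                   truth$env$mask)
  write_esri_ascii(truth$ndvi_change, truth$env$grid,
                   file.path(dir, "ndvi_change.asc"), truth$env$mask)
  invisible(dir)
}
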