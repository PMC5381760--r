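#' Local equal-area (equirectangular) projection to km
#'
#' Projects lon/lat to a planar km system centred on the data, adequate for
#' the distance computations behind buffering, kernel estimation and
#' nearest-neighbour statistics at subcontinental spans.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param ref optional list with `lon0`, `lat0` (defaults to data means).
#' @return list with `x`, `y` (km) and the `ref` used.
#' @export
project_local_km <- function(lon, lat, ref = NULL) {
  if (is.null(ref)) ref <- list(lon0 = mean(lon), lat0 = mean(lat))
  kx <- 111.32 * cos(ref$lat0 * pi / 180)
  ky <- 110.574
  list(x = (lon - ref$lon0) * kx, y = (lat - ref$lat0) * ky,
       ref = c(ref, list(kx = kx, ky = ky)))
}

#' Effectively sampled area: merged buffers around the records
#'
#' Buffers every record by `buffer_km` and merges the buffers into a single
#' study region. The region is represented as a raster mask on a planar-km
#' working grid (the environment provides no polygon geometry engine), with
#' area obtained by cell counting; the resolution is chosen so the longest
#' grid side has about `target_cells` cells.
#'
#' @param records record table (or data.frame with `lon`, `lat`).
#' @param buffer_km buffer radius in km (default 200).
#' @param target_cells approximate cell count along the longest side.
#' @return a `study_polygon`: planar `grid` (km), logical `mask`, projected
#'   `points`, `area_km2`, `buffer_km`, projection `ref`.
#' @export
build_study_polygon <- function(records, buffer_km = 200, target_cells = 220) {
  stopifnot(nrow(records) >= 1)
  pr <- project_local_km(records$lon, records$lat)
  pad <- buffer_km * 1.02
  xr <- range(pr$x) + c(-pad, pad)
  yr <- range(pr$y) + c(-pad, pad)
  cell <- max(diff(xr), diff(yr)) / target_cells
  nc <- ceiling(diff(xr) / cell)
  nr <- ceiling(diff(yr) / cell)
  grid <- env_grid(nr, nc, xr[1], yr[1], cell, crs = "planar_km")
  cc <- cell_centers(grid)
  inside <- rep(FALSE, nr * nc)
  for (i in seq_along(pr$x)) {   # mark cells within the buffer of each point
    cand <- which(!inside &
                    abs(cc$x - pr$x[i]) <= buffer_km &
                    abs(cc$y - pr$y[i]) <= buffer_km)
    if (length(cand)) {
      d2 <- (cc$x[cand] - pr$x[i])^2 + (cc$y[cand] - pr$y[i])^2
      inside[cand[d2 <= buffer_km^2]] <- TRUE
    }
  }
  structure(list(grid = grid, mask = matrix(inside, nr, nc),
                 points = data.frame(x = pr$x, y = pr$y),
                 area_km2 = sum(inside) * cell^2,
                 buffer_km = buffer_km, ref = pr$ref),
            class = "study_polygon")
}

#' @export
print.study_polygon <- function(x, ...) {
  cat(sprintf("<study_polygon> %d points, buffer %g km, area %.0f km2 (%d x %d grid, cell %.1f km)\n",
              nrow(x$points), x$buffer_km, x$area_km2,
              x$grid$nrow, x$grid$ncol, x$grid$cellsize))
  invisible(x)
}

# Scott's plug-in bandwidth per coordinate for a bivariate Gaussian kernel
scott_bandwidth <- function(x, y) {
  n <- length(x)
  c(h_x = stats::sd(x) * n^(-1 / 6), h_y = stats::sd(y) * n^(-1 / 6))
}

#' Kernel estimate of sampling intensity over the study region
#'
#' Gaussian product kernel evaluated at the cell centres of the study-region
#' grid, normalised so the intensity integrates to the observed point count.
#' Bandwidth `"auto"` uses Scott's plug-in rule per coordinate
#' (`sd * n^(-1/6)`).
#'
#' @param records record table or data.frame with `lon`/`lat` (projected with
#'   the polygon's reference), or a data.frame with planar `x`/`y` km.
#' @param polygon a `study_polygon`.
#' @param bandwidth `"auto"` or numeric length-2 (km).
#' @return a `kernel_intensity`: `values` matrix (points per km^2, `NA` off
#'   region), `grid`, `bandwidth`, `n`.
#' @export
fit_kernel_intensity <- function(records, polygon, bandwidth = "auto") {
  pts <- polygon_points(records, polygon)
  if (nrow(pts) < 2) stop("need at least 2 points for a kernel estimate")
  if (stats::sd(pts$x) == 0 && stats::sd(pts$y) == 0)
    stop("all points identical; kernel intensity is degenerate")
  if (identical(bandwidth, "auto")) bandwidth <- scott_bandwidth(pts$x, pts$y)
  h <- pmax(bandwidth, 1e-6)
  grid <- polygon$grid
  cc <- cell_centers(grid)
  keep <- as.vector(polygon$mask)
  w <- rep(0, length(cc$x))
  for (i in seq_len(nrow(pts)))
    w[keep] <- w[keep] +
      exp(-0.5 * (((cc$x[keep] - pts$x[i]) / h[1])^2 +
                    ((cc$y[keep] - pts$y[i]) / h[2])^2))
  n <- nrow(pts)
  cellarea <- grid$cellsize^2
  lambda <- rep(NA_real_, length(w))
  lambda[keep] <- n * (w[keep] / sum(w[keep])) / cellarea
  structure(list(values = matrix(lambda, grid$nrow, grid$ncol), grid = grid,
                 bandwidth = h, n = n),
            class = "kernel_intensity")
}

# accepts lon/lat records (projected via polygon ref) or planar x/y
polygon_points <- function(records, polygon) {
  if (!is.null(records$x) && !is.null(records$y))
    return(data.frame(x = records$x, y = records$y))
  pr <- project_local_km(records$lon, records$lat,
                         ref = polygon$ref[c("lon0", "lat0")])
  data.frame(x = pr$x, y = pr$y)
}

#' Simulate a point set from a kernel intensity
#'
#' Cells are drawn with probability proportional to intensity, then points
#' are jittered uniformly within the cell.
#' @param intensity a `kernel_intensity`.
#' @param n number of points.
#' @return data.frame with planar `x`, `y` (km).
#' @export
simulate_from_intensity <- function(intensity, n) {
  v <- as.vector(intensity$values)
  ok <- which(!is.na(v) & v > 0)
  cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = v[ok])]
  grid <- intensity$grid
  row <- (cells - 1L) %% grid$nrow + 1L
  col <- (cells - 1L) %/% grid$nrow + 1L
  cs <- grid$cellsize
  data.frame(
    x = grid$xmin + (col - 1L) * cs + runif(n) * cs,
    y = grid$ymin + (grid$nrow - row) * cs + runif(n) * cs)
}

#' Empirical nearest-neighbour distance CDF (G-function)
#'
#' Uncorrected estimator: the ECDF of each point's distance to its nearest
#' neighbour, evaluated on a fixed distance grid. No edge correction is
#' applied — the same estimator is used for observed and simulated patterns,
#' so Monte Carlo comparisons remain fair.
#'
#' @param x,y planar coordinates (km).
#' @param r distance grid.
#' @return numeric vector of G values on `r` (nondecreasing, in [0, 1]).
#' @export
g_function <- function(x, y, r) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  vapply(r, function(ri) mean(nnd <= ri), numeric(1))
}

#' Monte Carlo complete-spatial-randomness test with a kernel-guided null
#'
#' Tests whether a point pattern is consistent with an inhomogeneous Poisson
#' null whose intensity is a multivariate kernel estimate of sampling effort.
#' `n_sim` conditional simulations (fixed at the observed n) are drawn from
#' the intensity; the summary statistic is the maximum absolute deviation of
#' the nearest-neighbour G-function from the pooled null mean over a distance
#' grid (Kolmogorov-type). Deviations are computed leave-one-out over the
#' exchangeable pool of observed + simulated patterns, making the Monte Carlo
#' p-value exactly uniform under the null:
#' `p = (1 + #\{sims with deviation >= observed\}) / (n_sim + 1)`.
#'
#' @param records record table (lon/lat) or planar data.frame.
#' @param polygon a `study_polygon` delimiting the effectively sampled area.
#' @param n_sim number of simulations (>= 39; default 500).
#' @param seed RNG seed.
#' @param intensity optional pre-fitted `kernel_intensity`; by default the
#'   kernel is fitted to the records themselves (or to `effort_records`).
#' @param effort_records optional record set defining sampling effort (e.g.
#'   both phenotypes combined) when testing one phenotype's pattern.
#' @param bandwidth kernel bandwidth passed to [fit_kernel_intensity()].
#' @param r_grid_n number of distance-grid points (default 512).
#' @return a `csr_result`: `p_value`, `deviation_stat`, `g_observed`,
#'   `g_null_mean`, `g_null_envelope` (per-distance min/max over sims), `r`,
#'   `n_sim`, `seed`.
#' @export
csr_test <- function(records, polygon, n_sim = 500, seed = 1,
                     intensity = NULL, effort_records = NULL,
                     bandwidth = "auto", r_grid_n = 512) {
  pts <- polygon_points(records, polygon)
  if (nrow(pts) < 3) stop("need at least 3 points for the CSR test")
  if (n_sim < 39) stop("n_sim must be >= 39 for a meaningful envelope")
  if (is.null(intensity)) {
    eff <- if (is.null(effort_records)) records else effort_records
    intensity <- fit_kernel_intensity(eff, polygon, bandwidth)
  }
  set.seed(seed)
  n <- nrow(pts)
  sims <- replicate(n_sim, simulate_from_intensity(intensity, n),
                    simplify = FALSE)
  # common distance grid: generous upper bound from observed + null NN scale
  d_obs <- as.matrix(stats::dist(pts)); diag(d_obs) <- Inf
  rmax <- 3 * max(apply(d_obs, 1, min))
  r <- seq(0, rmax, length.out = r_grid_n)
  g_all <- vapply(c(list(pts), sims),
                  function(p) g_function(p$x, p$y, r), numeric(r_grid_n))
  total <- rowSums(g_all)
  m <- ncol(g_all)            # n_sim + 1 curves, column 1 = observed
  dev <- vapply(seq_len(m), function(k)
    max(abs(g_all[, k] - (total - g_all[, k]) / (m - 1))), numeric(1))
  p <- (1 + sum(dev[-1] >= dev[1])) / (n_sim + 1)
  structure(list(
    p_value = p, deviation_stat = dev[1],
    g_observed = g_all[, 1],
    g_null_mean = rowMeans(g_all[, -1, drop = FALSE]),
    g_null_envelope = cbind(low = apply(g_all[, -1], 1, min),
                            high = apply(g_all[, -1], 1, max)),
    r = r, n_sim = n_sim, seed = seed, n = n),
    class = "csr_result")
}

#' @export
print.csr_result <- function(x, ...) {
  cat(sprintf("<csr_result> n = %d, %d simulations: deviation = %.4f, p = %.4g\n",
              x$n, x$n_sim, x$deviation_stat, x$p_value))
  invisible(x)
}
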