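#' Named spatial scale for driver contrasts
#'
#' A scale is a named rectangular extent (or explicit cell mask) on the
#' analysis grid; records and cells are assigned to every scale whose region
#' contains them (scales may nest, mirroring full range / intermediate /
#' restricted designs).
#'
#' @param name label.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`, or `NULL` with `mask`.
#' @param mask optional logical matrix on the analysis grid.
#' @export
scale_definition <- function(name, extent = NULL, mask = NULL) {
  if (is.null(extent) && is.null(mask)) stop("give an extent or a mask")
  structure(list(name = name, extent = extent, mask = mask),
            class = "scale_definition")
}

in_scale <- function(scale, x, y, grid = NULL) {
  if (!is.null(scale$extent)) {
    e <- scale$extent
    return(x >= e[1] & x <= e[2] & y >= e[3] & y <= e[4])
  }
  idx <- cell_from_xy(grid, x, y)
  !is.na(idx) & as.vector(scale$mask)[ifelse(is.na(idx), 1L, idx)]
}

#' Environmental driver contrasts between phenotype models across scales
#'
#' For every scale and environmental variable, computes each phenotype
#' model's suitability-weighted mean of the variable over the shared record
#' set, and tests the difference with a paired t-test at record level: the
#' pair for record i is the variable value weighted by that record's
#' normalised suitability under each model
#' (`v_i * s_i / mean(s)`; the mean of these terms is exactly the
#' suitability-weighted mean). Significance flags use a Bonferroni-adjusted
#' threshold `alpha / (n_variables x n_scales)`. The same shared record set
#' also yields per-phenotype least-squares slope and Pearson R of
#' suitability against each variable (and against an NDVI layer when given).
#'
#' @param records record table (all phenotypes pooled: both models are
#'   interrogated at the same points).
#' @param env an `env_stack`.
#' @param suit_minor,suit_major suitability matrices for the melanistic and
#'   non-melanistic models on the env grid.
#' @param scales list of [scale_definition()]s.
#' @param alpha family-wise error rate (default 0.05).
#' @param ndvi optional NDVI matrix on the env grid, added as a regressor.
#' @return a `driver_contrast`: per scale x variable rows with weighted
#'   means, paired t, p, Bonferroni flag, and per-phenotype slope/R.
#' @export
driver_contrast <- function(records, env, suit_minor, suit_major, scales,
                            alpha = 0.05, ndvi = NULL) {
  grid <- env$grid
  vars <- names(env$layers)
  n_tests <- length(vars) * length(scales)
  thr <- alpha / n_tests
  idx <- cell_from_xy(grid, records$lon, records$lat)
  rows <- list()
  for (sc in scales) {
    ins <- in_scale(sc, records$lon, records$lat, grid) & !is.na(idx)
    sm <- suit_minor[idx[ins]]; sM <- suit_major[idx[ins]]
    ok <- !is.na(sm) & !is.na(sM)
    if (sum(ok) < 3) {
      warning("scale '", sc$name, "' has <3 usable records; skipped")
      next
    }
    sm <- sm[ok]; sM <- sM[ok]
    sub_idx <- idx[ins][ok]
    wm_minor <- sm / mean(sm); wm_major <- sM / mean(sM)
    reg_vars <- c(stats::setNames(lapply(vars, function(v)
      env$layers[[v]][sub_idx]), vars),
      if (!is.null(ndvi)) list(ndvi = ndvi[sub_idx]))
    for (v in vars) {
      vv <- reg_vars[[v]]
      d <- vv * wm_minor - vv * wm_major
      tt <- if (stats::sd(d) == 0) list(t = 0, p = 1) else {
        ts <- mean(d) / (stats::sd(d) / sqrt(length(d)))
        list(t = ts, p = 2 * stats::pt(-abs(ts), df = length(d) - 1))
      }
      rows[[length(rows) + 1]] <- data.frame(
        scale = sc$name, variable = v, n = length(d),
        mean_minor = mean(vv * wm_minor), mean_major = mean(vv * wm_major),
        t = tt$t, p = tt$p, significant = tt$p < thr)
    }
    regs <- lapply(names(reg_vars), function(v) {
      vv <- reg_vars[[v]]
      slope_r <- function(s) {
        if (stats::sd(vv) == 0 || stats::sd(s) == 0)
          return(c(slope = 0, R = 0))
        c(slope = stats::cov(s, vv) / stats::var(vv), R = stats::cor(s, vv))
      }
      a <- slope_r(sm); b <- slope_r(sM)
      data.frame(scale = sc$name, variable = v,
                 slope_minor = a["slope"], R_minor = a["R"],
                 slope_major = b["slope"], R_major = b["R"],
                 row.names = NULL)
    })
    attr(rows[[length(rows)]], "reg") <- do.call(rbind, regs)
  }
  contrasts <- do.call(rbind, rows)
  regressions <- do.call(rbind, lapply(rows, attr, "reg"))
  structure(list(contrasts = contrasts, regressions = regressions,
                 alpha = alpha, n_tests = n_tests, threshold = thr),
            class = "driver_contrast")
}

#' @export
print.driver_contrast <- function(x, ...) {
  cat(sprintf("<driver_contrast> %d tests, Bonferroni threshold %.4g\n",
              x$n_tests, x$threshold))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Barrier moisture-contrast test
#'
#' Samples equal numbers of random points north and south of a latitudinal
#' barrier, restricted to one biome class, extracts a target variable, and
#' compares the two sides with a two-sample t-test (the classic design: 600
#' points split exactly 50/50 across the barrier, all inside the moist
#' tropical forest class).
#'
#' @param env an `env_stack`.
#' @param barrier_y latitude (grid y) of the barrier; cells with centre
#'   above it are "north".
#' @param biomes integer biome matrix on the env grid.
#' @param biome_class class code defining eligible cells.
#' @param variable layer name to contrast (default `"moisture"`).
#' @param n_points total points (must be even; default 600).
#' @param seed RNG seed.
#' @return a `barrier_result` with side means, t, dof, p, and the sampled
#'   cell values.
#' @export
barrier_contrast <- function(env, barrier_y, biomes, biome_class,
                             variable = "moisture", n_points = 600, seed = 1) {
  if (n_points %% 2 != 0) stop("n_points must be even (exact 50/50 split)")
  half <- n_points / 2
  cc <- cell_centers(env$grid)
  eligible <- as.vector(env$mask) & !is.na(as.vector(biomes)) &
    as.vector(biomes) == biome_class
  north <- which(eligible & cc$y > barrier_y)
  south <- which(eligible & cc$y <= barrier_y)
  if (length(north) < half)
    stop("insufficient eligible cells north of the barrier: need ", half,
         ", have ", length(north))
  if (length(south) < half)
    stop("insufficient eligible cells south of the barrier: need ", half,
         ", have ", length(south))
  set.seed(seed)
  sn <- sample(north, half)
  ss <- sample(south, half)
  v <- as.vector(env$layers[[variable]])
  vn <- v[sn]; vs <- v[ss]
  tt <- stats::t.test(vs, vn)   # south minus north
  structure(list(variable = variable, n_points = n_points,
                 mean_north = mean(vn), mean_south = mean(vs),
                 t = unname(tt$statistic), dof = unname(tt$parameter),
                 p = tt$p.value, values_north = vn, values_south = vs,
                 seed = seed),
            class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("<barrier_result> %s, %d points: south %.3f vs north %.3f, t = %.2f (dof %.1f), p = %.3g\n",
              x$variable, x$n_points, x$mean_south, x$mean_north, x$t, x$dof,
              x$p))
  invisible(x)
}

#' Leave-region-out robustness check
#'
#' Refits a phenotype model after excluding all presences inside a region
#' and reports the mean suitability within that region before vs after the
#' exclusion — high retained suitability indicates the regional signal is
#' shared with records elsewhere rather than an artefact of local sampling.
#' With a region disjoint from all records the refit is bit-identical to the
#' original (same seed, same RNG path).
#'
#' @param presences presence points (`lon`/`lat`).
#' @param env an `env_stack`.
#' @param region a [scale_definition()].
#' @param protocol a [maxent_protocol()].
#' @param seed RNG seed.
#' @return list with `map_full`, `map_loro`, `region_mean_before`,
#'   `region_mean_after`, `ratio`, `n_excluded`.
#' @export
leave_region_out <- function(presences, env, region,
                             protocol = maxent_protocol(), seed = 1) {
  inside <- in_scale(region, presences$lon, presences$lat, env$grid)
  if (all(inside)) stop("region covers every presence; nothing left to fit")
  bg <- sample_background(env, protocol$n_background,
                          seed = stage_seed(seed, "lorobg"))
  fit_map <- function(pts) {
    set.seed(stage_seed(seed, "lorofit"))
    fit <- fit_maxent(pts, bg, env = env, features = protocol$features,
                      reg_multiplier = protocol$reg_multiplier,
                      max_iter = protocol$max_iter, tol = protocol$tol,
                      n_hinge = protocol$n_hinge)
    predict(fit, env)
  }
  map_full <- fit_map(presences)
  map_loro <- fit_map(presences[!inside, , drop = FALSE])
  cc <- cell_centers(env$grid)
  reg_cells <- in_scale(region, cc$x, cc$y, env$grid) & as.vector(env$mask)
  before <- mean(map_full[reg_cells], na.rm = TRUE)
  after <- mean(map_loro[reg_cells], na.rm = TRUE)
  list(map_full = map_full, map_loro = map_loro,
       region_mean_before = before, region_mean_after = after,
       ratio = after / before, n_excluded = sum(inside))
}
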