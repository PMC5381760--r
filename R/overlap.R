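#' Niche overlap statistics between two suitability maps
#'
#' Both maps are normalised to sum 1 over their shared valid cells (p, q);
#' then
#' * Schoener's `D = 1 - 0.5 * sum |p - q|`,
#' * Hellinger-based `I = 1 - 0.5 * sum (sqrt(p) - sqrt(q))^2`,
#' * relative rank `RR` = probability, over cell pairs, that the two maps
#'   order the pair identically (a tie in either map counts as agreement).
#'
#' `RR` is computed exhaustively when the number of cell pairs is below
#' `exhaustive_limit`, otherwise by seeded sampling of `n_sample_pairs`
#' random pairs.
#'
#' @param map1,map2 aligned suitability matrices (NA = nodata).
#' @param exhaustive_limit pair-count threshold for exhaustive RR
#'   (default 2e6).
#' @param n_sample_pairs sampled pairs when above the limit (default 1e6).
#' @param seed seed for pair sampling.
#' @return list with `D`, `I`, `RR`, `n_cells`, `rr_method`.
#' @export
overlap_statistics <- function(map1, map2, exhaustive_limit = 2e6,
                               n_sample_pairs = 1e6, seed = 1) {
  if (!all(dim(map1) == dim(map2))) stop("maps are not aligned")
  shared <- !is.na(map1) & !is.na(map2)
  p <- as.vector(map1)[shared]
  q <- as.vector(map2)[shared]
  if (!length(p)) stop("maps share no valid cells")
  if (all(p == 0) || all(q == 0)) stop("all-zero suitability map")
  if (any(p < 0) || any(q < 0)) stop("negative suitability values")
  p <- p / sum(p); q <- q / sum(q)
  D <- 1 - 0.5 * sum(abs(p - q))
  I <- 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
  n <- length(p)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= exhaustive_limit) {
    rr_method <- "exhaustive"
    RR <- rr_exhaustive(p, q)
  } else {
    rr_method <- "sampled"
    set.seed(seed)
    i <- sample.int(n, n_sample_pairs, replace = TRUE)
    j <- sample.int(n, n_sample_pairs, replace = TRUE)
    ok <- i != j
    sp <- sign(p[i[ok]] - p[j[ok]])
    sq <- sign(q[i[ok]] - q[j[ok]])
    RR <- mean(sp == sq | sp == 0 | sq == 0)
  }
  list(D = D, I = I, RR = RR, n_cells = n, rr_method = rr_method)
}

# exhaustive pairwise rank agreement in blocks (memory-bounded)
rr_exhaustive <- function(p, q, block = 500L) {
  n <- length(p)
  agree <- 0; total <- 0
  for (start in seq(1L, n - 1L, by = block)) {
    idx <- start:min(start + block - 1L, n - 1L)
    for (i in idx) {
      j <- (i + 1L):n
      sp <- sign(p[i] - p[j]); sq <- sign(q[i] - q[j])
      agree <- agree + sum(sp == sq | sp == 0 | sq == 0)
      total <- total + length(j)
    }
  }
  agree / total
}

#' Default lightweight model protocol for resampling experiments
#'
#' Bundles the fitting knobs used by the equivalency null and the
#' leave-region-out refits; defaults are desk-scale (small background,
#' linear+quadratic features) so hundreds of refits stay affordable.
#' @param features feature classes (default linear+quadratic).
#' @param n_background background size per fit.
#' @param max_iter,tol,reg_multiplier,n_hinge see [fit_maxent()].
#' @param rr_pairs sampled pairs for null RR values (smaller than the
#'   observed-statistic estimator; the null only needs rank resolution).
#' @export
maxent_protocol <- function(features = c("linear", "quadratic"),
                            n_background = 2000, max_iter = 200, tol = 1e-5,
                            reg_multiplier = 1, n_hinge = 20,
                            rr_pairs = 20000) {
  list(features = features, n_background = n_background, max_iter = max_iter,
       tol = tol, reg_multiplier = reg_multiplier, n_hinge = n_hinge,
       rr_pairs = rr_pairs)
}

#' Niche equivalency test with a resampled null distribution
#'
#' Observed D/I/RR are computed between the two phenotypes' suitability maps
#' (by default the mean maps over [run_replicates()] fits under `protocol`).
#' The null mimics phenotype-label uninformativeness at the observed class
#' imbalance: `n_replicates` pseudo-minor models of size
#' `round(frac_minor * n_major)` and `n_replicates` pseudo-major models of
#' size `round((1 - frac_minor) * n_minor)`; D/I/RR over all
#' `n_replicates^2` cross pairs form the null. One-sided p-values ask
#' whether observed overlap is lower than the null:
#' `p = (1 + #\{null <= observed\}) / (n_null + 1)`.
#'
#' Two resampling schemes are available. `"pooled"` (default, the classic
#' niche-identity null): pseudo records of both directions are drawn from
#' the pooled record set, so under label-exchangeability the null reproduces
#' the observed comparison and under a real niche difference the pooled
#' models converge on the mixture niche, leaving the observed overlap in the
#' null's lower tail. `"reciprocal"`: pseudo-minor records are drawn from
#' the majority set and pseudo-major records from the minority set. The
#' reciprocal null is itself a cross-niche comparison, so when pseudo and
#' observed models carry similar information its distribution tracks the
#' observed statistic even under a true difference — it detects sample-size
#' asymmetry rather than niche difference, and is provided for protocol
#' comparison only (see the methods vignette).
#'
#' @param pres_minor,pres_major presence points for the minority
#'   (melanistic) and majority (non-melanistic) phenotype.
#' @param env an `env_stack`.
#' @param n_replicates null replicates per direction (default 100; the
#'   null size is its square).
#' @param frac_minor minority fraction (default 0.10).
#' @param protocol a [maxent_protocol()].
#' @param null_scheme `"pooled"` (default) or `"reciprocal"`; see Details.
#' @param seed RNG seed.
#' @param observed optional precomputed list with maps `minor` and `major`;
#'   fitted under `protocol` when omitted.
#' @param n_model_replicates replicates per observed mean map (default 5).
#' @param two_sided also report two-sided p-values.
#' @return an `overlap_result`: observed `D`, `I`, `RR`, null samples,
#'   p-values, `n_null`.
#' @export
equivalency_test <- function(pres_minor, pres_major, env, n_replicates = 100,
                             frac_minor = 0.10, protocol = maxent_protocol(),
                             null_scheme = c("pooled", "reciprocal"),
                             seed = 1, observed = NULL,
                             n_model_replicates = 5, two_sided = FALSE) {
  null_scheme <- match.arg(null_scheme)
  n_min <- nrow(pres_minor); n_maj <- nrow(pres_major)
  k_pseudo_minor <- round(frac_minor * n_maj)        # sampled from majority
  k_pseudo_major <- round((1 - frac_minor) * n_min)  # sampled from minority
  if (k_pseudo_major < 2 || n_min - k_pseudo_major < 0 || k_pseudo_minor < 2)
    stop("minority group too small: need >= ", ceiling(2 / (1 - frac_minor)),
         " minority records and >= ", ceiling(2 / frac_minor),
         " majority records")
  bg <- sample_background(env, protocol$n_background,
                          seed = stage_seed(seed, "eqbg"))
  fit_map <- function(pts) {
    fit <- fit_maxent(pts, bg, env = env, features = protocol$features,
                      reg_multiplier = protocol$reg_multiplier,
                      max_iter = protocol$max_iter, tol = protocol$tol,
                      n_hinge = protocol$n_hinge)
    predict(fit, env)
  }
  if (is.null(observed)) {
    obs_minor <- run_replicates(pres_minor, env, n_replicates = n_model_replicates,
                                seed = stage_seed(seed, "obs_minor"),
                                background = bg, features = protocol$features,
                                max_iter = protocol$max_iter, tol = protocol$tol,
                                reg_multiplier = protocol$reg_multiplier,
                                n_hinge = protocol$n_hinge,
                                response_curve_n = 0)$mean_suitability
    obs_major <- run_replicates(pres_major, env, n_replicates = n_model_replicates,
                                seed = stage_seed(seed, "obs_major"),
                                background = bg, features = protocol$features,
                                max_iter = protocol$max_iter, tol = protocol$tol,
                                reg_multiplier = protocol$reg_multiplier,
                                n_hinge = protocol$n_hinge,
                                response_curve_n = 0)$mean_suitability
  } else {
    obs_minor <- observed$minor; obs_major <- observed$major
  }
  obs <- overlap_statistics(obs_minor, obs_major, seed = stage_seed(seed, "obsrr"))

  set.seed(stage_seed(seed, "eqnull"))
  shared <- intersect(names(pres_minor), names(pres_major))
  pool <- rbind(pres_minor[, shared, drop = FALSE],
                pres_major[, shared, drop = FALSE])
  if (null_scheme == "pooled") {
    maps_pseudo_minor <- lapply(seq_len(n_replicates), function(i)
      fit_map(pool[sample.int(nrow(pool), k_pseudo_minor), , drop = FALSE]))
    maps_pseudo_major <- lapply(seq_len(n_replicates), function(i)
      fit_map(pool[sample.int(nrow(pool), k_pseudo_major), , drop = FALSE]))
  } else {
    maps_pseudo_minor <- lapply(seq_len(n_replicates), function(i)
      fit_map(pres_major[sample.int(n_maj, k_pseudo_minor), , drop = FALSE]))
    maps_pseudo_major <- lapply(seq_len(n_replicates), function(i)
      fit_map(pres_minor[sample.int(n_min, k_pseudo_major), , drop = FALSE]))
  }

  n_null <- n_replicates^2
  null_D <- null_I <- null_RR <- numeric(n_null)
  k <- 0L
  for (i in seq_len(n_replicates)) for (j in seq_len(n_replicates)) {
    k <- k + 1L
    ov <- overlap_statistics(maps_pseudo_minor[[i]], maps_pseudo_major[[j]],
                             exhaustive_limit = 0,
                             n_sample_pairs = protocol$rr_pairs,
                             seed = stage_seed(seed, paste0("nullrr", k)))
    null_D[k] <- ov$D; null_I[k] <- ov$I; null_RR[k] <- ov$RR
  }
  pval <- function(obs_v, null_v) (1 + sum(null_v <= obs_v)) / (length(null_v) + 1)
  p2 <- function(obs_v, null_v) {
    lo <- (1 + sum(null_v <= obs_v)) / (length(null_v) + 1)
    hi <- (1 + sum(null_v >= obs_v)) / (length(null_v) + 1)
    min(1, 2 * min(lo, hi))
  }
  pf <- if (two_sided) p2 else pval
  structure(list(
    D = obs$D, I = obs$I, RR = obs$RR,
    null_D = null_D, null_I = null_I, null_RR = null_RR,
    p_D = pf(obs$D, null_D), p_I = pf(obs$I, null_I), p_RR = pf(obs$RR, null_RR),
    n_null = n_null, n_replicates = n_replicates, frac_minor = frac_minor,
    null_scheme = null_scheme, two_sided = two_sided, seed = seed,
    observed_maps = list(minor = obs_minor, major = obs_major)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> D = %.3f (p = %.4g), I = %.3f (p = %.4g), RR = %.3f (p = %.4g); null n = %d%s\n",
              x$D, x$p_D, x$I, x$p_I, x$RR, x$p_RR, x$n_null,
              if (x$two_sided) " (two-sided)" else ""))
  invisible(x)
}

#' Serialise an overlap result (including full null samples) to JSON
#' @param x an `overlap_result`.
#' @param path optional output file.
#' @export
overlap_result_json <- function(x, path = NULL) {
  keep <- c("D", "I", "RR", "p_D", "p_I", "p_RR", "n_null", "n_replicates",
            "frac_minor", "null_scheme", "two_sided", "seed",
            "null_D", "null_I", "null_RR")
  j <- jsonlite::toJSON(unclass(x)[keep], auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(j, path)
  invisible(j)
}

#' Paired suitability comparison at shared records
#'
#' Extracts, for every record, the suitability under both phenotype models
#' and runs a paired t-test on the per-record differences. Records on nodata
#' in either map are dropped pairwise (and counted). A zero-variance zero
#' difference (identical maps) yields `t = 0`, `p = 1` by convention.
#'
#' @param records record table (lon/lat) or planar points matching the grid.
#' @param mapA,mapB suitability matrices on `grid`.
#' @param grid the shared `env_grid`.
#' @return a `suitability_comparison`.
#' @export
paired_suitability_test <- function(records, mapA, mapB, grid) {
  xs <- if (!is.null(records$lon)) records$lon else records$x
  ys <- if (!is.null(records$lat)) records$lat else records$y
  idx <- cell_from_xy(grid, xs, ys)
  a <- rep(NA_real_, length(idx)); b <- a
  a[!is.na(idx)] <- mapA[idx[!is.na(idx)]]
  b[!is.na(idx)] <- mapB[idx[!is.na(idx)]]
  ok <- !is.na(a) & !is.na(b)
  n_dropped <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("need at least 2 records on valid cells of both maps")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- 0; p <- 1
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(
    suitability_A = a, suitability_B = b,
    mean_A = mean(a), sd_A = stats::sd(a),
    mean_B = mean(b), sd_B = stats::sd(b),
    mean_difference = mean(d), t = t_stat, dof = n - 1, p = p,
    n = n, n_dropped = n_dropped),
    class = "suitability_comparison")
}

#' @export
print.suitability_comparison <- function(x, ...) {
  cat(sprintf("<suitability_comparison> n = %d: mean A = %.3f (sd %.3f), mean B = %.3f (sd %.3f), t = %.3f (dof %d), p = %.3g\n",
              x$n, x$mean_A, x$sd_A, x$mean_B, x$sd_B, x$t, x$dof, x$p))
  invisible(x)
}
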