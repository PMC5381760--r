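#' Correlation-based predictor pre-selection
#'
#' Samples unique random valid cells, computes pairwise Pearson correlations
#' among layers over the sample, and greedily retains a subset such that no
#' retained pair exceeds the cutoff: while any pair with `|r| > r_cutoff`
#' remains, the layer with the most over-threshold partners is dropped (ties
#' broken by larger mean `|r|` against all layers, then by name order).
#'
#' @param env an `env_stack`.
#' @param range_mask optional logical matrix restricting the sampling area.
#' @param n_points points to sample (default 10000; capped with a warning at
#'   the number of available valid cells).
#' @param r_cutoff absolute correlation cutoff (default 0.7).
#' @param seed RNG seed.
#' @return character vector of retained layer names (attribute `"cor"` holds
#'   the sampled correlation matrix).
#' @export
select_predictors <- function(env, range_mask = NULL, n_points = 10000,
                              r_cutoff = 0.7, seed = 1) {
  if (length(env$layers) < 2) stop("need at least 2 layers")
  ok <- as.vector(env$mask)
  if (!is.null(range_mask)) ok <- ok & as.vector(range_mask)
  cells <- which(ok)
  if (n_points > length(cells)) {
    warning("requested ", n_points, " points but only ", length(cells),
            " valid cells; sampling all of them")
    n_points <- length(cells)
  }
  set.seed(seed)
  s <- sample(cells, n_points)
  vals <- vapply(env$layers, function(m) m[s], numeric(n_points))
  cm <- stats::cor(vals)
  keep <- colnames(cm)
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    over <- rowSums(sub > r_cutoff)
    if (all(over == 0)) break
    worst <- which(over == max(over))
    if (length(worst) > 1) {
      mr <- rowMeans(sub)[worst]
      worst <- worst[mr == max(mr)]
      if (length(worst) > 1) worst <- worst[order(names(worst))[1]]
    }
    keep <- setdiff(keep, names(worst)[1])
  }
  structure(keep, cor = cm)
}

#' Uniform background sample over valid cells
#'
#' @param env an `env_stack`.
#' @param n_background points to draw (without replacement; capped with a
#'   warning at the valid-cell count).
#' @param seed RNG seed.
#' @return data.frame with `x`, `y` (cell centres) and one column per layer.
#' @export
sample_background <- function(env, n_background = 10000, seed = 1) {
  cells <- which(as.vector(env$mask))
  if (n_background > length(cells)) {
    warning("requested ", n_background, " background points but only ",
            length(cells), " valid cells; using all of them")
    n_background <- length(cells)
  }
  set.seed(seed)
  s <- sample(cells, n_background)
  cc <- cell_centers(env$grid)
  out <- data.frame(x = cc$x[s], y = cc$y[s])
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][s]
  out
}

# ---- feature machinery -----------------------------------------------------

# Auto feature classes mirroring the classic Maxent schedule by sample size
# (no threshold features).
auto_feature_classes <- function(m) {
  if (m < 10) "linear"
  else if (m < 15) c("linear", "quadratic")
  else if (m < 80) c("linear", "quadratic", "hinge")
  else c("linear", "quadratic", "product", "hinge")
}

# Build the feature definition from raw layer values (bounds from the
# training extent: background plus presences).
make_feature_defs <- function(classes, layer_names, bounds, n_hinge = 50) {
  defs <- list(classes = classes, layers = layer_names, bounds = bounds,
               n_hinge = n_hinge)
  if ("hinge" %in% classes)
    defs$knots <- seq(0, 1, length.out = n_hinge + 2)[2:(n_hinge + 1)]
  defs
}

# raw layer matrix -> standardized [0,1] with clamping to training bounds
standardize_layers <- function(X, bounds, clamp = TRUE) {
  Z <- sweep(sweep(X, 2, bounds[1, ], "-"), 2, bounds[2, ] - bounds[1, ], "/")
  if (clamp) Z[] <- pmin(pmax(Z, 0), 1)
  Z
}

# feature matrix from standardized layers; column classes as attribute
build_features <- function(Z, defs) {
  L <- ncol(Z)
  cols <- list(); classes <- character(0); nms <- character(0)
  if ("linear" %in% defs$classes) {
    cols <- c(cols, list(Z))
    classes <- c(classes, rep("linear", L))
    nms <- c(nms, defs$layers)
  }
  if ("quadratic" %in% defs$classes) {
    cols <- c(cols, list(Z^2))
    classes <- c(classes, rep("quadratic", L))
    nms <- c(nms, paste0(defs$layers, "^2"))
  }
  if ("product" %in% defs$classes && L >= 2) {
    for (a in seq_len(L - 1)) for (b in seq((a + 1), L)) {
      cols <- c(cols, list(Z[, a] * Z[, b, drop = FALSE]))
      classes <- c(classes, "product")
      nms <- c(nms, paste0(defs$layers[a], "*", defs$layers[b]))
    }
  }
  if ("hinge" %in% defs$classes) {
    for (l in seq_len(L)) {
      for (k in defs$knots) {
        fwd <- pmax(0, (Z[, l] - k) / (1 - k))
        rev <- pmax(0, (k - Z[, l]) / k)
        cols <- c(cols, list(cbind(fwd, rev)))
        classes <- c(classes, "hinge", "hinge")
        nms <- c(nms, paste0(defs$layers[l], c(">", "<"), round(k, 3)))
      }
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nms
  attr(F, "classes") <- classes
  F
}

# classic per-class regularization schedule interpolated on sample size
beta_class <- function(class, m) {
  interp <- function(xs, ys) {
    if (m <= xs[1]) return(ys[1])
    if (m >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = m)$y
  }
  switch(class,
         linear = , quadratic = , product = interp(c(10, 30, 100), c(1, 0.2, 0.05)),
         hinge = 0.5,
         threshold = interp(c(10, 100), c(2, 1)),
         0.05)
}

#' Fit a maximum-entropy presence-background model
#'
#' Maximum-entropy density estimation over the background cells: the raw
#' output is the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over
#' background, with `lambda` maximising the L1-penalised log-likelihood of
#' the presences,
#' `(1/m) sum_i lambda . f(x_i) - log Z - sum_j beta_j |lambda_j|`.
#' Features are standardised to [0, 1] over the training extent;
#' `beta_j = reg_multiplier * beta_class(m) * sqrt(var_j(presences) / m)`
#' with the classic per-class schedules. Optimisation is FISTA-style
#' accelerated proximal gradient with backtracking on the convex objective —
#' the objective, not any particular sequential-update algorithm, defines
#' the model. Convergence: relative objective change below `tol`.
#'
#' @param presences data.frame with `x`, `y` (or `lon`, `lat`) of presence
#'   points, or a matrix/data.frame of layer values.
#' @param background background point set from [sample_background()], or a
#'   matrix/data.frame of layer values.
#' @param env an `env_stack` (used to extract values when point coordinates
#'   are supplied).
#' @param features `"auto"` (classic schedule on the presence count) or a
#'   character subset of `linear`, `quadratic`, `product`, `hinge`.
#' @param reg_multiplier multiplier on the regularisation schedule.
#' @param max_iter iteration cap (default 500).
#' @param tol relative convergence threshold (default 1e-5).
#' @param n_hinge hinge knots per layer (default 50).
#' @return a `maxent_model` with feature definitions, weights, normaliser,
#'   entropy, clamp bounds and training metadata.
#' @export
fit_maxent <- function(presences, background, env = NULL, features = "auto",
                       reg_multiplier = 1, max_iter = 500, tol = 1e-5,
                       n_hinge = 50) {
  Xp <- point_values(presences, env)
  Xb <- point_values(background, env)
  layer_names <- colnames(Xb)
  keep <- stats::complete.cases(Xp)
  Xp <- Xp[keep, , drop = FALSE]
  if (nrow(Xp) < 2) stop("need at least 2 presences on valid cells")
  if (any(!is.finite(as.matrix(Xb))) || any(!is.finite(as.matrix(Xp)))) {
    bad <- layer_names[apply(!is.finite(rbind(as.matrix(Xp), as.matrix(Xb))),
                             2, any)]
    stop("non-finite values in layer(s): ", paste(bad, collapse = ", "))
  }
  m <- nrow(Xp)
  if (identical(features, "auto")) features <- auto_feature_classes(m)
  bounds <- rbind(min = pmin(apply(Xb, 2, min), apply(Xp, 2, min)),
                  max = pmax(apply(Xb, 2, max), apply(Xp, 2, max)))
  rng <- bounds[2, ] - bounds[1, ]
  bounds[2, rng == 0] <- bounds[1, rng == 0] + 1   # constant layer guard
  defs <- make_feature_defs(features, layer_names, bounds, n_hinge)
  Fb <- build_features(standardize_layers(as.matrix(Xb), bounds), defs)
  Fp <- build_features(standardize_layers(as.matrix(Xp), bounds), defs)
  classes <- attr(Fb, "classes")
  fbar <- colMeans(Fp)
  s2 <- apply(Fp, 2, stats::var)
  beta <- reg_multiplier *
    vapply(classes, beta_class, numeric(1), m = m) * sqrt(pmax(s2, 1e-8) / m)

  J <- ncol(Fb)
  lam <- numeric(J)
  eta <- rep(0, nrow(Fb))
  logZ <- log(nrow(Fb))
  smooth_obj <- function(eta) {
    mx <- max(eta)
    mx + log(sum(exp(eta - mx)))
  }
  obj_val <- function(lam, eta) smooth_obj(eta) - sum(fbar * lam) +
    sum(beta * abs(lam))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  f0 <- obj_val(lam, eta)
  step <- 1
  y <- lam; ty <- 1
  obj_trace <- f0
  converged <- FALSE
  iters <- 0L
  lam_prev <- lam
  for (it in seq_len(max_iter)) {
    iters <- it
    eta_y <- as.vector(Fb %*% y)
    mx <- max(eta_y)
    w <- exp(eta_y - mx); w <- w / sum(w)
    grad <- as.vector(crossprod(Fb, w)) - fbar
    g_y <- smooth_obj(eta_y) - sum(fbar * y)
    repeat {  # backtracking on the smooth part
      lam_new <- soft(y - step * grad, step * beta)
      d <- lam_new - y
      eta_new <- as.vector(Fb %*% lam_new)
      g_new <- smooth_obj(eta_new) - sum(fbar * lam_new)
      if (g_new <= g_y + sum(grad * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    t_new <- (1 + sqrt(1 + 4 * ty^2)) / 2
    f_new <- g_new + sum(beta * abs(lam_new))
    if (f_new > obj_trace[length(obj_trace)]) {  # restart acceleration
      y <- lam_prev; ty <- 1
      eta_y <- as.vector(Fb %*% y)
      next
    }
    y <- lam_new + ((ty - 1) / t_new) * (lam_new - lam_prev)
    ty <- t_new
    rel <- abs(obj_trace[length(obj_trace)] - f_new) /
      (abs(obj_trace[length(obj_trace)]) + 1e-12)
    obj_trace <- c(obj_trace, f_new)
    lam_prev <- lam_new
    if (rel < tol) { converged <- TRUE; break }
  }
  lam <- lam_prev
  eta_b <- as.vector(Fb %*% lam)
  mxb <- max(eta_b)
  qb <- exp(eta_b - mxb); qb <- qb / sum(qb)
  H <- -sum(qb * log(pmax(qb, 1e-300)))
  logZ <- mxb + log(sum(exp(eta_b - mxb)))
  structure(list(
    feature_defs = defs, weights = stats::setNames(lam, colnames(Fb)),
    feature_classes = classes, beta = beta, log_Z = logZ, entropy = H,
    raw_background = qb, obj_trace = obj_trace,
    train_meta = list(n_presence = m, n_background = nrow(Fb),
                      iterations_run = iters, converged = converged,
                      features = features, reg_multiplier = reg_multiplier,
                      tol = tol)),
    class = "maxent_model")
}

# resolve point sets to layer-value matrices
point_values <- function(pts, env) {
  if (is.matrix(pts)) return(pts)
  if (!is.null(env) && !is.null(pts$lon) && !is.null(pts$lat))
    return(as.matrix(extract_env(env, pts$lon, pts$lat)))
  if (!is.null(env) && !is.null(pts$x) && !is.null(pts$y) &&
      !all(names(env$layers) %in% names(pts)))
    return(as.matrix(extract_env(env, pts$x, pts$y)))
  lay <- setdiff(names(pts), c("x", "y", "lon", "lat"))
  as.matrix(pts[, lay, drop = FALSE])
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("<maxent_model> %d/%d nonzero features [%s], m = %d, %d iterations (%s), H = %.3f\n",
              nz, length(x$weights),
              paste(x$train_meta$features, collapse = "+"),
              x$train_meta$n_presence, x$train_meta$iterations_run,
              if (x$train_meta$converged) "converged" else "not converged",
              x$entropy))
  invisible(x)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' Raw output is the Gibbs density relative to the training background
#' (`exp(lambda . f(x)) / Z`); the logistic output transforms it with the
#' model entropy H, `e^H q / (1 + e^H q)`, giving values in (0, 1) with an
#' implied prevalence of 0.5. Features are clamped to the training bounds.
#'
#' @param object a `maxent_model`.
#' @param env an `env_stack` (returns a raster matrix), or a data.frame /
#'   matrix of layer values (returns a vector).
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return matrix on the env grid, or numeric vector.
#' @export
predict.maxent_model <- function(object, env, type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  defs <- object$feature_defs
  if (inherits(env, "env_stack")) {
    miss <- setdiff(defs$layers, names(env$layers))
    if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
    X <- vapply(defs$layers, function(nm) as.vector(env$layers[[nm]]),
                numeric(n_cells(env$grid)))
    out_mask <- as.vector(env$mask)
  } else {
    X <- as.matrix(as.data.frame(env)[, defs$layers, drop = FALSE])
    out_mask <- rep(TRUE, nrow(X))
  }
  F <- build_features(standardize_layers(X, defs$bounds), defs)
  raw <- exp(as.vector(F %*% object$weights) - object$log_Z)
  val <- if (type == "raw") raw else {
    eh <- exp(object$entropy) * raw
    eh / (1 + eh)
  }
  val[!out_mask] <- NA
  if (inherits(env, "env_stack"))
    matrix(val, env$grid$nrow, env$grid$ncol)
  else val
}

#' Presence-background AUC (rank / Mann-Whitney estimator with ties)
#' @param pos suitability at test presences.
#' @param neg suitability at background points.
#' @export
auc_background <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Replicated model runs with the classic 70/30 protocol
#'
#' Per replicate: a random 70/30 presence split, model fit on the training
#' share, test AUC against the background sample, and a suitability map.
#' Outputs the per-cell mean suitability across replicates, the AUC mean and
#' standard error, permutation variable importance (mean AUC drop when one
#' layer's values are shuffled across the evaluation points, floored at zero
#' and normalised to percentages), and per-layer response curves (one layer
#' swept over its observed range, the others held at the training-presence
#' mean).
#'
#' @param presences presence point data.frame (`lon`/`lat` or `x`/`y`).
#' @param env an `env_stack`.
#' @param train_fraction training share (default 0.7).
#' @param n_replicates replicate count (default 10 at desk scale;
#'   configurable up to the classic 500).
#' @param seed RNG seed.
#' @param background optional pre-drawn background (default: 10000 or all
#'   valid cells, whichever is smaller).
#' @param n_background background size when `background` is NULL.
#' @param features,reg_multiplier,max_iter,tol,n_hinge passed to
#'   [fit_maxent()].
#' @param response_curve_n points per response curve (0 disables).
#' @return list with `mean_suitability` (matrix), `evaluation` (a
#'   `model_evaluation`), and `models` (the fitted replicates).
#' @export
run_replicates <- function(presences, env, train_fraction = 0.7,
                           n_replicates = 10, seed = 1, background = NULL,
                           n_background = 10000, features = "auto",
                           reg_multiplier = 1, max_iter = 500, tol = 1e-5,
                           n_hinge = 50, response_curve_n = 50) {
  if (is.null(background))
    background <- sample_background(env, n_background, seed = stage_seed(seed, "bg"))
  Xall <- point_values(presences, env)
  ok <- stats::complete.cases(Xall)
  Xall <- Xall[ok, , drop = FALSE]
  m <- nrow(Xall)
  if (m < 4) stop("need at least 4 presences on valid cells")
  Xbg <- point_values(background, env)
  set.seed(stage_seed(seed, "replicates"))
  n_train <- max(2, floor(train_fraction * m))
  if (m - n_train < 2 && m > 4) {
    warning("train fraction leaves <2 test presences; shrinking training set")
    n_train <- m - 2
  }
  aucs <- numeric(n_replicates)
  sum_map <- 0
  models <- vector("list", n_replicates)
  imp_acc <- matrix(0, n_replicates, ncol(Xall),
                    dimnames = list(NULL, colnames(Xall)))
  for (rep_i in seq_len(n_replicates)) {
    tr <- sample.int(m, n_train)
    te <- setdiff(seq_len(m), tr)
    if (length(te) < 2) { te <- tr }  # tiny-sample fallback: test on train
    fit <- fit_maxent(Xall[tr, , drop = FALSE], Xbg, features = features,
                      reg_multiplier = reg_multiplier, max_iter = max_iter,
                      tol = tol, n_hinge = n_hinge)
    models[[rep_i]] <- fit
    pred_te <- predict(fit, Xall[te, , drop = FALSE])
    pred_bg <- predict(fit, Xbg)
    aucs[rep_i] <- auc_background(pred_te, pred_bg)
    sum_map <- sum_map + predict(fit, env)
    # permutation importance over the evaluation set
    eval_X <- rbind(Xall[te, , drop = FALSE], Xbg)
    n_pos <- length(te)
    for (v in seq_len(ncol(Xall))) {
      Xperm <- eval_X
      Xperm[, v] <- sample(Xperm[, v])
      pp <- predict(fit, Xperm)
      auc_p <- auc_background(pp[seq_len(n_pos)], pp[-seq_len(n_pos)])
      imp_acc[rep_i, v] <- max(0, aucs[rep_i] - auc_p)
    }
  }
  drops <- colMeans(imp_acc)
  importance <- if (sum(drops) > 0) 100 * drops / sum(drops) else
    rep(100 / length(drops), length(drops))
  names(importance) <- colnames(Xall)
  curves <- NULL
  if (response_curve_n > 0) {
    mean_tr <- colMeans(Xall)
    curves <- lapply(seq_len(ncol(Xall)), function(v) {
      grid_v <- seq(min(Xbg[, v]), max(Xbg[, v]), length.out = response_curve_n)
      Xc <- matrix(rep(mean_tr, each = response_curve_n),
                   nrow = response_curve_n,
                   dimnames = list(NULL, colnames(Xall)))
      Xc[, v] <- grid_v
      data.frame(value = grid_v,
                 suitability = rowMeans(vapply(models, function(mo)
                   predict(mo, Xc), numeric(response_curve_n))))
    })
    names(curves) <- colnames(Xall)
  }
  evaluation <- structure(list(
    auc = aucs, auc_mean = mean(aucs),
    auc_se = stats::sd(aucs) / sqrt(n_replicates),
    variable_importance = importance, response_curves = curves,
    n_replicates = n_replicates, n_presence = m,
    n_background = nrow(Xbg), seed = seed),
    class = "model_evaluation")
  list(mean_suitability = sum_map / n_replicates, evaluation = evaluation,
       models = models)
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %d replicates, n = %d: mean AUC = %.3f (se %.3f)\n",
              x$n_replicates, x$n_presence, x$auc_mean, x$auc_se))
  imp <- sort(x$variable_importance, decreasing = TRUE)
  cat("  importance (%):", paste(sprintf("%s %.1f", names(imp), imp),
                                 collapse = ", "), "\n")
  invisible(x)
}
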