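test_that("select_predictors drops one of a highly correlated pair", {
  tc <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3)
  cfg <- synthetic_config(seed = 15, grid_shape = c(50, 50), target_corr = tc,
                          layer_names = c("l1", "l2", "l3"))
  env <- generate_env_stack(cfg)
  kept <- select_predictors(env, n_points = 2000, seed = 2)
  expect_equal(length(kept), 2)
  expect_true("l3" %in% kept)
  expect_equal(sum(c("l1", "l2") %in% kept), 1)
  # brute-force check: sampled r of the generated pair really is above 0.7
  cm <- attr(kept, "cor")
  expect_gt(abs(cm["l1", "l2"]), 0.7)
  # independent layers: all retained
  cfg0 <- synthetic_config(seed = 16, grid_shape = c(50, 50),
                           target_corr = diag(3))
  expect_equal(length(select_predictors(generate_env_stack(cfg0),
                                        n_points = 2000)), 3)
  # duplicated layer dropped deterministically
  dup <- env_stack(list(a = env$layers$l1, a_copy = env$layers$l1,
                        c = env$layers$l3), env$grid)
  k1 <- select_predictors(dup, n_points = 1000, seed = 1)
  k2 <- select_predictors(dup, n_points = 1000, seed = 1)
  expect_identical(as.character(k1), as.character(k2))
  expect_equal(sum(c("a", "a_copy") %in% k1), 1)
  # oversized request capped with a warning
  expect_warning(select_predictors(env, n_points = 1e6), "valid cells")
})

test_that("sample_background draws unique valid cells reproducibly", {
  env <- tiny_env(40, seed = 2)
  bg1 <- sample_background(env, 500, seed = 9)
  bg2 <- sample_background(env, 500, seed = 9)
  expect_identical(bg1, bg2)
  expect_equal(nrow(bg1), 500)
  expect_equal(anyDuplicated(bg1[, c("x", "y")]), 0)
  expect_warning(bgall <- sample_background(env, 5000, seed = 1), "valid")
  expect_equal(nrow(bgall), 1600)
})

test_that("maxent recovers a generating exponential coefficient", {
  set.seed(20)
  errs <- vapply(1:3, function(s) {
    set.seed(s)
    xbg <- matrix(runif(4000), ncol = 1, dimnames = list(NULL, "x1"))
    w <- exp(2 * xbg[, 1])
    xp <- matrix(xbg[sample(4000, 2000, replace = TRUE, prob = w), 1],
                 ncol = 1, dimnames = list(NULL, "x1"))
    fit <- fit_maxent(xp, xbg, features = "linear")
    abs(fit$weights[["x1"]] - 2) / 2
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})

test_that("maxent normalisation, logistic bounds and no-signal flatness", {
  set.seed(21)
  xbg <- matrix(cbind(runif(1500), runif(1500)), ncol = 2,
                dimnames = list(NULL, c("u", "v")))
  xp <- xbg[sample(1500, 300), , drop = FALSE]
  fit <- fit_maxent(xp, xbg, features = c("linear", "quadratic"))
  expect_equal(sum(fit$raw_background), 1, tolerance = 1e-8)
  pred <- predict(fit, xbg)
  expect_true(all(pred > 0 & pred < 1))
  # uniform presences: logistic output nearly constant, near 0.5
  expect_lt(diff(range(pred)), 0.1)
  expect_equal(mean(pred), 0.5, tolerance = 0.1)
  # penalized objective is nonincreasing along the optimizer path
  expect_true(all(diff(fit$obj_trace) <= 1e-10))
})

test_that("prediction is monotone in a single-layer monotone truth", {
  set.seed(22)
  xbg <- matrix(runif(2000), ncol = 1, dimnames = list(NULL, "x1"))
  xp <- matrix(xbg[sample(2000, 800, replace = TRUE,
                          prob = exp(3 * xbg[, 1])), 1],
               ncol = 1, dimnames = list(NULL, "x1"))
  fit <- fit_maxent(xp, xbg, features = "linear")
  grid_vals <- matrix(seq(0.02, 0.98, length.out = 50), ncol = 1,
                      dimnames = list(NULL, "x1"))
  pred <- predict(fit, grid_vals)
  expect_true(all(diff(pred) > 0))
  # clamping: values beyond training bounds saturate, no explosion
  pred_out <- predict(fit, matrix(c(-5, 5), ncol = 1,
                                  dimnames = list(NULL, "x1")))
  expect_equal(pred_out[1], predict(fit, matrix(0, 1, 1,
                                                dimnames = list(NULL, "x1")))[1],
               tolerance = 1e-9)
})

test_that("separable data without regularisation drives AUC towards 1", {
  set.seed(23)
  xbg <- matrix(runif(1000), ncol = 1, dimnames = list(NULL, "x1"))
  xp <- matrix(runif(200, 0.9, 1), ncol = 1, dimnames = list(NULL, "x1"))
  fit <- fit_maxent(xp, xbg, features = "linear", reg_multiplier = 0,
                    max_iter = 2000, tol = 1e-9)
  auc <- auc_background(predict(fit, xp), predict(fit, xbg))
  expect_gt(auc, 0.93)
})

test_that("auc_background matches wilcox.test on tied and untied data", {
  set.seed(24)
  pos <- c(rnorm(30, 1), 0.5, 0.5)
  neg <- c(rnorm(50), 0.5)
  w <- wilcox.test(pos, neg, exact = FALSE)$statistic
  expect_equal(auc_background(pos, neg), unname(w) / (32 * 51),
               tolerance = 1e-12)
})

test_that("replicated runs: informative truth scores high, noise scores 0.5", {
  cfg <- strong_niche_config(seed = 30, n_records = 250, grid = c(50, 50))
  tr <- generate_records(cfg)
  rr <- run_replicates(tr$records, tr$env, n_replicates = 4, seed = 5,
                       n_background = 1500)
  expect_gt(rr$evaluation$auc_mean, 0.8)
  expect_equal(sum(rr$evaluation$variable_importance), 100, tolerance = 0.1)
  # the zero-coefficient layer ranks below both informative layers
  imp <- rr$evaluation$variable_importance
  expect_true(imp["elevation"] < imp["moisture"] &&
                imp["elevation"] < imp["temperature"])
  # mean suitability raster shape and range
  expect_equal(dim(rr$mean_suitability), c(50, 50))
  expect_true(all(rr$mean_suitability > 0 & rr$mean_suitability < 1,
                  na.rm = TRUE))
  # uninformative world: white-noise layers (iid env values), uniform
  # presences -> AUC about 0.5
  cfg0 <- synthetic_config(seed = 32, grid_shape = c(50, 50), n_records = 2,
                           autocorr_range = 0)
  env0 <- generate_env_stack(cfg0)
  set.seed(31)
  unif <- data.frame(lon = runif(400, 0, 2.5), lat = runif(400, 0, 2.5))
  rr0 <- run_replicates(unif, env0, n_replicates = 4, seed = 6,
                        n_background = 1500)
  expect_lt(abs(rr0$evaluation$auc_mean - 0.5), 0.05)
})

test_that("fit_maxent input contracts", {
  xbg <- matrix(runif(100), ncol = 1, dimnames = list(NULL, "x1"))
  expect_error(fit_maxent(xbg[1, , drop = FALSE], xbg), "at least 2")
  bad <- xbg; bad[5] <- Inf
  expect_error(fit_maxent(xbg[1:10, , drop = FALSE], bad), "x1")
})
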