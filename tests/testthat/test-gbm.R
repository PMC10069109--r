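test_that("random search respects the grids and the seed", {
  sp <- gbm_search_space(max_models = 50, rng_seed = 4)
  cfg <- sample_search_space(sp)
  expect_lte(nrow(cfg), 50)
  expect_true(all(cfg$ntree %% 20 == 0 & cfg$ntree >= 100 & cfg$ntree <= 3000))
  expect_true(all(cfg$learn_rate %in% seq(0, 1, by = 0.1)))
  expect_true(all(cfg$max_depth %in% seq(5, 80, by = 5)))
  expect_true(all(cfg$min_leaf %in% seq(20, 100, by = 20)))
  expect_identical(cfg, sample_search_space(sp))
  # exhaustive duplicate-free enumeration when the grid is small
  tiny <- gbm_search_space(ntree = c(100, 120), learn_rate = c(0.1, 0.2),
                           max_depth = 5, min_leaf = 20, max_models = 100)
  cfg2 <- sample_search_space(tiny)
  expect_equal(nrow(cfg2), 4)
  expect_equal(nrow(dplyr::distinct(cfg2)), 4)
})

test_that("zero learning rate degenerates to the training-mean model", {
  set.seed(1)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- X[, 1] + rnorm(200, 0, 0.2)
  f0 <- gbm_fit(X, y, learn_rate = 0)
  expect_equal(unique(predict(f0, X)), mean(y))
  expect_error(variable_importance(f0), class = "spectrakin_undefined_error")
  # never selected when a real configuration is available
  sp <- gbm_search_space(ntree = 100, learn_rate = c(0, 0.3), max_depth = 5,
                         min_leaf = 20, max_models = 2, rng_seed = 1)
  fit <- gbm_tune(X, y, sp)
  expect_gt(attr(fit, "chosen")$learn_rate, 0)
})

test_that("training loss is non-increasing over boosting iterations", {
  set.seed(2)
  X <- matrix(rnorm(300 * 5), 300, 5)
  y <- X[, 2]^2 + rnorm(300, 0, 0.3)
  fit <- gbm_fit(X, y, ntree = 100, learn_rate = 0.2, max_depth = 5,
                 min_leaf = 20)
  log <- fit$evaluation_log
  expect_true(all(diff(log$train_rmse) <= 1e-10))
})

test_that("a noiseless step function is recovered almost perfectly", {
  set.seed(3)
  X <- matrix(runif(600 * 3), 600, 3)
  y <- ifelse(X[, 1] > 0.5, 4, -1)
  tr <- 1:400
  sp <- gbm_search_space(ntree = c(100, 200), learn_rate = c(0.1, 0.5),
                         max_depth = 5, min_leaf = 20, max_models = 4,
                         rng_seed = 2)
  fit <- gbm_tune(X[tr, ], y[tr], sp)
  pred <- predict(fit, X[-tr, ])
  expect_gt(cor(y[-tr], pred)^2, 0.95)
})

test_that("pure-noise responses give near-zero out-of-sample skill", {
  set.seed(4)
  X <- matrix(rnorm(1000 * 10), 1000, 10)
  y <- rnorm(1000)
  tr <- 1:700
  sp <- gbm_search_space(ntree = 100, learn_rate = c(0.1, 0.3), max_depth = 5,
                         min_leaf = 20, max_models = 2, rng_seed = 3)
  fit <- gbm_tune(X[tr, ], y[tr], sp)
  pred <- predict(fit, X[-tr, ])
  r2 <- if (sd(pred) == 0) 0 else cor(y[-tr], pred)^2
  expect_lt(r2, 0.05)
})

test_that("variable importance sums to 100 and respects column structure", {
  set.seed(5)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- sprintf("f%d", 1:6)
  y <- 2 * X[, 3] + X[, 5] + rnorm(n, 0, 0.3)
  fit <- gbm_fit(X, y, ntree = 80, learn_rate = 0.2, max_depth = 3,
                 min_leaf = 20)
  vi <- variable_importance(fit)
  expect_equal(sum(vi$vi), 100, tolerance = 1e-6)
  expect_true(all(vi$vi >= 0))
  expect_equal(vi$feature[which.max(vi$vi)], "f3")
  # permuting the feature columns permutes the importances
  perm <- c(4, 2, 6, 1, 5, 3)
  Xp <- X[, perm]
  colnames(Xp) <- sprintf("f%d", 1:6)  # positional names
  fitp <- gbm_fit(Xp, y, ntree = 80, learn_rate = 0.2, max_depth = 3,
                  min_leaf = 20)
  vip <- variable_importance(fitp)
  expect_equal(vip$vi, vi$vi[perm], tolerance = 1e-6)
  # duplicated columns share the total importance
  Xd <- cbind(X, f3bis = X[, 3])
  fitd <- gbm_fit(Xd, y, ntree = 80, learn_rate = 0.2, max_depth = 3,
                  min_leaf = 20)
  vid <- variable_importance(fitd)
  shared <- sum(vid$vi[vid$feature %in% c("f3", "f3bis")])
  expect_equal(shared, vi$vi[vi$feature == "f3"], tolerance = 1)
})

test_that("significant wavelength selection applies the percent threshold", {
  vi_uniform <- tibble::tibble(feature = sprintf("w%d", 1:1060),
                               vi = rep(100 / 1060, 1060))
  expect_length(significant_wavelengths(vi_uniform), 0)
  vi_single <- tibble::tibble(feature = c("a", "b"), vi = c(100, 0))
  expect_equal(significant_wavelengths(vi_single), "a")
  ov <- vi_overlap(list(x = c("a", "b", "c"), y = c("b", "c", "d")))
  expect_equal(ov$overlap, 2)
  expect_equal(ov$jaccard, 0.5)
})

test_that("planted spectral windows dominate the selected wavelengths", {
  picked <- vapply(1:3, function(seed) {
    cfg <- sim_config(
      n_cows = 250, herd_sizes = c(200, 50), n_snps = 40, n_wavelengths = 100,
      traits = tibble::tibble(trait = "y", mean = 0, sd = 1,
                              h2_target = 0.2, hbatch_target = 0.1),
      spectral_signal = 0.9, batch_spectral_sd = 0, outlier_frac = 0,
      rng_seed = 100 + seed)
    ds <- simulate_dataset(cfg)
    pre <- preprocess_spectra(ds$spectra, alpha = 1e-6)
    X <- spectra_values(pre$spectra)
    ct <- ds$cow_table[match(rownames(X), ds$cow_table$cow_id), ]
    fit <- gbm_fit(X, ct$y, ntree = 100, learn_rate = 0.2, max_depth = 4,
                   min_leaf = 20)
    vi <- variable_importance(fit)
    sel <- significant_wavelengths(vi, threshold = 0.8)
    if (length(sel) == 0) return(NA_real_)
    inside <- ds$truth$spectral_windows[match(sel, vi$feature), 1]
    mean(inside)
  }, numeric(1))
  expect_gte(median(picked, na.rm = TRUE), 0.8)
})
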