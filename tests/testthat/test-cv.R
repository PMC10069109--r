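test_that("tenfold folds are balanced, disjoint and exhaustive", {
  ids <- sprintf("c%04d", 1:1019)
  sch <- cv_tenfold(ids, seed = 3)
  sizes <- vapply(sch$validation, length, integer(1))
  expect_equal(sum(sizes), 1019)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sort(unlist(sch$validation)), sort(ids))  # each validated once
  for (r in 1:10) {
    expect_length(intersect(sch$train[[r]], sch$validation[[r]]), 0)
  }
  expect_identical(sch, cv_tenfold(ids, seed = 3))
  small <- cv_tenfold(sprintf("c%d", 1:20), seed = 1)
  expect_true(all(vapply(small$validation, length, integer(1)) == 2))
  expect_error(cv_tenfold(sprintf("c%d", 1:5), seed = 1),
               class = "spectrakin_config_error")
})

test_that("batch-out validation covers every batch across replicates", {
  sb <- small_bundle()
  ct <- sb$bundle$cow_table
  G <- sb$bundle$G
  rownames(G) <- colnames(G) <-
    ct$cow_id[match(rownames(G), as.character(ct$animal))]
  sch <- cv_batch_out(ct$cow_id, ct$batch, G, n_replicates = 5)
  expect_equal(nrow(sch), 5)
  covered <- sort(unique(unlist(sch$validation_batches)))
  expect_equal(covered, sort(unique(ct$batch)))
  # whole batches only, train/validation batch-disjoint
  for (r in 1:5) {
    vb <- sch$validation_batches[[r]]
    expect_setequal(sch$validation[[r]], ct$cow_id[ct$batch %in% vb])
    tb <- unique(ct$batch[ct$cow_id %in% sch$train[[r]]])
    expect_length(intersect(tb, vb), 0)
  }
  # degenerate identical batches still satisfy the coverage invariant
  ids <- sprintf("x%02d", 1:40)
  G0 <- diag(40); dimnames(G0) <- list(ids, ids)
  sch0 <- cv_batch_out(ids, rep(1:4, each = 10), G0, n_replicates = 4)
  expect_equal(sort(unlist(sch0$validation_batches)), 1:4)
})

test_that("batch-out spreads the genomically most distant batches first", {
  # two planted clusters: batches 1-2 far from batches 3-6
  set.seed(6)
  n <- 60
  ids <- sprintf("c%02d", 1:n)
  batches <- rep(1:6, each = 10)
  base <- matrix(rnorm(n * n, 0, 0.01), n, n)
  far <- as.numeric(batches %in% 1:2)
  G <- diag(n) + outer(far, far) * 2 + (base + t(base)) / 2
  dimnames(G) <- list(ids, ids)
  sch <- cv_batch_out(ids, batches, G, n_replicates = 3)
  # the two far batches land in different replicates (round-robin by distance)
  reps_of_far <- vapply(1:2, function(b) {
    which(vapply(sch$validation_batches, function(v) b %in% v, logical(1)))
  }, integer(1))
  expect_length(unique(reps_of_far), 2)
})

test_that("herd-out emits both directions and rejects non-two-herd data", {
  ids <- sprintf("c%03d", 1:100)
  herds <- rep(c(1, 2), c(80, 20))
  sch <- cv_herd_out(ids, herds)
  expect_equal(nrow(sch), 2)
  expect_length(sch$train[[1]], 80)
  expect_length(sch$validation[[1]], 20)
  expect_setequal(sch$train[[2]], sch$validation[[1]])
  for (r in 1:2) {
    expect_length(intersect(sch$train[[r]], sch$validation[[r]]), 0)
  }
  expect_error(cv_herd_out(ids, rep(1, 100)),
               class = "spectrakin_config_error")
})

test_that("evaluation statistics match hand oracles", {
  y <- c(1, 2, 3, 4)
  p <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(r_squared(y, p), cor(y, p)^2, tolerance = 1e-12)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, 2 * y + 3), 1)  # affine invariance
  expect_error(r_squared(y, rep(1, 4)), class = "spectrakin_undefined_error")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 2), 2)
  expect_equal(rmse(y, p), sqrt(sum((y - p)^2) / 4), tolerance = 1e-12)
  expect_error(rmse(y, p[1:3]), class = "spectrakin_data_error")

  expect_equal(calibration_slope(y, y), 1)
  expect_equal(calibration_slope(y, y / 2), 2)  # deflated predictions
  fit <- lm(y ~ p)
  expect_equal(calibration_slope(y, p), unname(coef(fit)[2]),
               tolerance = 1e-12)
  expect_error(calibration_slope(y, rep(1, 4)),
               class = "spectrakin_undefined_error")
})

test_that("relative differences reproduce the percent-gain formula", {
  expect_equal(relative_difference(0.63, 0.53), 18.867925, tolerance = 1e-6)
  expect_equal(relative_difference(0.5, 0.5), 0)
  expect_error(relative_difference(0.5, 0), class = "spectrakin_undefined_error")
  # antisymmetry: RD(a,b) = -100 * RD(b,a) / (100 + RD(b,a))
  for (pair in list(c(0.63, 0.53), c(0.4, 0.8), c(0.2, 0.15))) {
    rd_ab <- relative_difference(pair[1], pair[2])
    rd_ba <- relative_difference(pair[2], pair[1])
    expect_equal(rd_ab, -100 * rd_ba / (100 + rd_ba), tolerance = 1e-10)
  }
})

test_that("RD-on-heritability regression matches the OLS oracle", {
  h2 <- c(0.1, 0.2, 0.35, 0.5, 0.6)
  rd_lin <- 5 + 20 * h2
  # an exactly linear relation triggers R's perfect-fit note in summary()
  perfect <- suppressWarnings(rd_vs_h2_regression(rd_lin, h2))
  expect_equal(perfect$slope, 20, tolerance = 1e-10)
  expect_equal(perfect$intercept, 5, tolerance = 1e-10)
  expect_equal(perfect$r2, 1, tolerance = 1e-10)
  set.seed(12)
  rd_noise <- rnorm(60)
  h2_noise <- runif(60)
  expect_lt(rd_vs_h2_regression(rd_noise, h2_noise)$r2, 0.12)
  fit <- lm(rd_noise ~ h2_noise)
  got <- rd_vs_h2_regression(rd_noise, h2_noise)
  expect_equal(got$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_error(rd_vs_h2_regression(1:2, 1:2), class = "spectrakin_data_error")
})

test_that("wavelength-trait correlations behave at the extremes", {
  set.seed(13)
  X <- matrix(rnorm(200 * 3), 200, 3,
              dimnames = list(NULL, c("w1", "w2", "w3")))
  traits <- tibble::tibble(t1 = X[, 1], t2 = rnorm(200))
  tab <- wavelength_trait_correlations(X, traits)
  expect_equal(tab$correlation[tab$wavelength == "w1" & tab$trait == "t1"], 1)
  null_cors <- tab$correlation[tab$trait == "t2"]
  expect_true(all(abs(null_cors) < 4 / sqrt(200)))
  Xz <- cbind(X, wz = 0)
  expect_warning(wavelength_trait_correlations(Xz, traits),
                 "zero-variance")
})

test_that("the experiment factorial has the expected shape and fixed folds", {
  sb <- small_bundle()
  res <- run_experiment(
    sb$bundle, traits = "y", methods = "BayesB", models = c("M1", "M2"),
    schemes = "herd_out", seed = 2,
    bayesb_chain = chain_config(800, 200, 2, rng_seed = 2))
  expect_equal(nrow(res), 2 * 2)  # 2 replicates x 2 models
  expect_setequal(unique(res$model), c("M1", "M2"))
  s <- summarize_experiment(res)
  expect_equal(nrow(s), 2)
  # rerunning the baseline alone reproduces its cells (fold fixing)
  res_m1 <- run_experiment(
    sb$bundle, traits = "y", methods = "BayesB", models = "M1",
    schemes = "herd_out", seed = 2,
    bayesb_chain = chain_config(800, 200, 2, rng_seed = 2))
  expect_equal(res_m1$r2,
               res$r2[res$model == "M1"], tolerance = 1e-12)
})
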