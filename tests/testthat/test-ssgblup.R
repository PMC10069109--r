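test_that("heritability and batch incidence are the documented ratios", {
  expect_equal(heritability(0.25, 0.75), 0.25)
  expect_equal(heritability(0, 1), 0)
  expect_equal(batch_incidence(0.2, 0, 0.8), 0)
  expect_equal(batch_incidence(0.1, 0.3, 0.6), 0.3)
  # vectorized over posterior samples
  expect_equal(heritability(c(1, 2), c(1, 2)), c(0.5, 0.5))
  expect_error(heritability(0, 0), class = "spectrakin_undefined_error")
  expect_error(batch_incidence(0, 0, 0), class = "spectrakin_undefined_error")
  expect_error(heritability(-1, 2), class = "spectrakin_parameter_error")
})

test_that("Geweke diagnostic is calibrated on i.i.d. chains and detects drift", {
  set.seed(99)
  pvals <- replicate(500, geweke_diagnostic(rnorm(400))$p.value)
  rej <- mean(pvals < 0.05)
  expect_true(abs(rej - 0.05) < 0.03)
  # designed failure: step change in the mean
  expect_lt(geweke_diagnostic(c(rnorm(300), rnorm(300, 5)))$p.value, 0.05)
  expect_error(geweke_diagnostic(rnorm(50)),
               class = "spectrakin_insufficient_samples_error")
  expect_error(geweke_diagnostic(rep(1, 200)),
               class = "spectrakin_degenerate_chain_error")
})

test_that("stored-sample count equals (n_iter - burn_in) / thin", {
  sb <- small_bundle()
  ch <- chain_config(2000, 500, 5, rng_seed = 1)
  fit <- animal_model_gibbs(sb$bundle$cow_table, "y", sb$bundle$kinship,
                            chain = ch)
  expect_equal(fit$n_stored, (2000 - 500) / 5)
  expect_equal(nrow(fit$samples), 300)
  expect_error(chain_config(1000, 2000, 5),
               class = "spectrakin_config_error")
})

test_that("heritability estimates are invariant to rescaling the phenotype", {
  sb <- small_bundle()
  ct <- sb$bundle$cow_table
  ch <- chain_config(2000, 500, 5, rng_seed = 7)
  f1 <- animal_model_gibbs(ct, "y", sb$bundle$kinship, chain = ch)
  ct$y10 <- 10 * ct$y
  f2 <- animal_model_gibbs(ct, "y10", sb$bundle$kinship, chain = ch)
  # same seed, proportional state: variance ratios match almost exactly
  expect_equal(f2$samples$h2, f1$samples$h2, tolerance = 1e-8)
  expect_equal(f2$samples$hbatch, f1$samples$hbatch, tolerance = 1e-8)
  expect_equal(mean(f2$samples$sigma2_a) / mean(f1$samples$sigma2_a), 100,
               tolerance = 1e-6)
})

test_that("with fixed variances the fixed-effect posterior matches GLS", {
  set.seed(11)
  n <- 120
  ped <- tibble::tibble(animal = 1:n, sire = 0, dam = 0)
  A <- build_A(ped)
  kin <- list(Hinv = chol2inv(chol(A)), id_order = rownames(A))
  s2a <- 0.5; s2e <- 1
  x <- rbinom(n, 1, 0.5)
  a_true <- rnorm(n, 0, sqrt(s2a))
  y <- 1 + 2 * x + a_true + rnorm(n, 0, sqrt(s2e))
  dat <- tibble::tibble(animal = 1:n, y = y, batch = 1,
                        dim_class = 1L, parity_class = x + 1L)
  fit <- animal_model_gibbs(dat, "y", kin,
                            chain = chain_config(20000, 2000, 5, rng_seed = 3),
                            fix_sigma2 = c(s2a, NA, s2e), use_batch = FALSE)
  V <- A * s2a + diag(n) * s2e
  X <- cbind(1, x)
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  b_hat <- colMeans(fit$b_samples)
  # Monte-Carlo tolerance: 3 batch-means standard errors
  mcse <- apply(fit$b_samples, 2, function(v) {
    bm <- tapply(v, rep(1:20, length.out = length(v)), mean)
    sd(bm) / sqrt(length(bm))
  })
  expect_true(all(abs(b_hat - as.numeric(b_gls)) < 3 * mcse + 1e-6))
})

test_that("posterior breeding values match pedigree-BLUP at fixed variances", {
  set.seed(21)
  ped <- random_pedigree(40, seed = 5)
  A <- build_A(ped)
  n <- nrow(ped)
  s2a <- 1; s2e <- 1
  y <- 3 + as.numeric(chol(A) %*% rnorm(n)) + rnorm(n)
  dat <- tibble::tibble(animal = ped$animal, y = y, batch = 1,
                        dim_class = 1L, parity_class = 1L)
  kin <- list(Hinv = chol2inv(chol(A)), id_order = rownames(A))
  fit <- animal_model_gibbs(dat, "y", kin,
                            chain = chain_config(30000, 3000, 5, rng_seed = 9),
                            fix_sigma2 = c(s2a, NA, s2e), use_batch = FALSE)
  # mixed-model equations with known variances
  lambda <- s2e / s2a
  X <- matrix(1, n, 1)
  Ai <- chol2inv(chol(A))
  C <- rbind(cbind(t(X) %*% X, t(X)),
             cbind(X, diag(n) + lambda * Ai))
  rhs <- c(sum(y), y)
  sol <- solve(C, rhs)
  a_blup <- sol[-1]
  expect_gt(cor(fit$a_mean, a_blup), 0.99)
  expect_lt(max(abs(fit$a_mean - a_blup)), 0.15)
})

test_that("null genetic signal concentrates the heritability posterior near zero", {
  cfg <- sim_config(
    n_cows = 1500, herd_sizes = c(1390, 110), n_snps = 500, n_wavelengths = 30,
    traits = tibble::tibble(trait = "null", mean = 0, sd = 1,
                            h2_target = 0, hbatch_target = 0.2),
    outlier_frac = 0, rng_seed = 31)
  ds <- simulate_dataset(cfg)
  geno <- genotype_qc(ds$genotypes)
  kin <- kinship_bundle(ds$pedigree, geno)
  fit <- animal_model_gibbs(ds$cow_table, "null", kin,
                            chain = chain_config(6000, 1500, 5, rng_seed = 1))
  expect_lt(glance(fit)$h2, 0.10)
})
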