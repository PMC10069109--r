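# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A compact single-trait population exercising every layer.
small_bundle <- function() {
  if (is.null(.fixtures$small_bundle)) {
    cfg <- sim_config(
      n_cows = 160, n_snps = 250, n_wavelengths = 90, n_batches = 8,
      herd_sizes = c(120, 40),
      traits = tibble::tibble(trait = "y", mean = 10, sd = 2,
                              h2_target = 0.4, hbatch_target = 0.2),
      outlier_frac = 0, rng_seed = 101)
    ds <- simulate_dataset(cfg)
    .fixtures$small_bundle <- list(
      config = cfg, dataset = ds,
      bundle = load_and_align(ds$cow_table, ds$spectra, ds$genotypes,
                              ds$pedigree))
  }
  .fixtures$small_bundle
}

# A random pedigree with overlapping generations for oracle checks.
random_pedigree <- function(n = 30, seed = 1) {
  set.seed(seed)
  animal <- seq_len(n)
  sire <- integer(n)
  dam <- integer(n)
  for (i in seq_len(n)) {
    if (i > 4 && runif(1) < 0.8) {
      prev <- seq_len(i - 1)
      sire[i] <- sample(prev, 1)
      dam[i] <- sample(setdiff(prev, sire[i]), 1)
    }
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# Gene-dropping estimate of the numerator relationship matrix: founders get
# two allelic values i.i.d. N(0, 1/2); offspring inherit one value from each
# parent; cov(u_i, u_j) over drops estimates A_ij.
gene_drop_A <- function(pedigree, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(pedigree)
  a1 <- matrix(0, n_drops, n)
  a2 <- matrix(0, n_drops, n)
  si <- match(pedigree$sire, pedigree$animal)
  di <- match(pedigree$dam, pedigree$animal)
  for (i in seq_len(n)) {
    if (is.na(si[i]) || pedigree$sire[i] == 0) {
      a1[, i] <- rnorm(n_drops, 0, sqrt(0.5))
    } else {
      pick <- runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, si[i]], a2[, si[i]])
    }
    if (is.na(di[i]) || pedigree$dam[i] == 0) {
      a2[, i] <- rnorm(n_drops, 0, sqrt(0.5))
    } else {
      pick <- runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, di[i]], a2[, di[i]])
    }
  }
  u <- a1 + a2
  crossprod(sweep(u, 2, colMeans(u))) / (n_drops - 1)
}
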