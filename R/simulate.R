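#' Default trait panel for the synthetic population
#'
#' Fifteen blood metabolites spanning energy metabolism, liver
#' function/hepatic damage, oxidative stress, inflammation/innate immunity
#' and minerals, with phenotypic means and SDs on their clinical scales and
#' per-trait targets for heritability (additive share of additive +
#' residual variance) and batch incidence (batch share of total phenotypic
#' variance). These values define the study conditions the generator
#' emulates; any subset can be selected, or a custom table supplied.
#'
#' @return A tibble with columns `trait`, `group`, `mean`, `sd`,
#'   `h2_target`, `hbatch_target`.
#' @export
default_trait_panel <- function() {
  tibble::tribble(
    ~trait,           ~group,          ~mean,   ~sd,   ~h2_target, ~hbatch_target,
    "glucose",        "energy",         4.35,   0.33,  0.360,      0.444,
    "bhba",           "energy",         0.53,   0.17,  0.125,      0.158,
    "urea",           "energy",         6.40,   1.05,  0.180,      0.361,
    "ast",            "liver",        100.65,  21.72,  0.360,      0.110,
    "ggt",            "liver",         28.36,   7.16,  0.427,      0.013,
    "pon",            "liver",         97.28,  19.29,  0.604,      0.076,
    "romt",           "oxidative",     12.70,   3.06,  0.130,      0.083,
    "aopp",           "oxidative",     48.05,   9.14,  0.089,      0.245,
    "frap",           "oxidative",    195.96,  36.62,  0.050,      0.244,
    "ceruloplasmin",  "inflammation",   1.90,   0.60,  0.374,      0.072,
    "prott",          "inflammation",  81.25,   4.82,  0.090,      0.066,
    "globulins",      "inflammation",  43.76,   5.36,  0.091,      0.065,
    "calcium",        "minerals",       2.51,   0.11,  0.125,      0.200,
    "potassium",      "minerals",       4.13,   0.41,  0.248,      0.286,
    "zinc",           "minerals",      12.02,   2.64,  0.346,      0.413
  )
}

#' Configuration for the synthetic dairy population
#'
#' Collects every knob of the generator: population size and herd split,
#' batch structure, marker and wavelength counts, the per-trait variance
#' targets, and the spectral-signal parameters. Defaults reproduce the
#' structure of the two-herd study population (1020 analysis cows split
#' 945/75 across herds, 16 herd-by-date batches, 1060 wavenumbers from 5011
#' to 925 cm-1), with the marker panel scaled to a desk-size 5000 SNPs.
#'
#' @param n_cows Number of study cows (the final pedigree generation).
#' @param n_snps Number of simulated SNPs.
#' @param n_wavelengths Number of FTIR wavenumbers (descending axis
#'   5011 to 925 cm-1).
#' @param n_batches Number of herd/date batches.
#' @param herd_sizes Integer vector of length 2; must sum to `n_cows`.
#' @param n_dim_classes,n_parity_classes Number of days-in-milk and parity
#'   classes for the fixed-effect layers.
#' @param traits Trait table as from [default_trait_panel()]; any data frame
#'   with columns `trait`, `mean`, `sd`, `h2_target`, `hbatch_target`.
#' @param spectral_signal Fraction in \[0, 1\] of each metabolite's
#'   non-batch phenotypic variance that is recoverable from the spectra.
#' @param qtl_frac Fraction of SNPs with nonzero effect per trait.
#' @param fixed_effect_scale Size of the DIM/parity class effects relative
#'   to the residual SD.
#' @param replicate_noise_sd Channel noise SD (absorbance units) added
#'   independently to each of the two replicate spectra per cow.
#' @param batch_spectral_sd SD of the smooth batch-level spectral drift,
#'   relative to the metabolite-signal amplitude.
#' @param outlier_frac Fraction of cows receiving gross spectral
#'   contamination (to exercise the Mahalanobis QC).
#' @param outlier_magnitude Size of the contamination in channel SDs.
#' @param n_generations Pedigree depth; 1 gives founders only.
#' @param rng_seed Integer seed; identical configurations yield
#'   bitwise-identical simulations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cows = 1020,
                       n_snps = 5000,
                       n_wavelengths = 1060,
                       n_batches = 16,
                       herd_sizes = c(945, 75),
                       n_dim_classes = 6,
                       n_parity_classes = 4,
                       traits = default_trait_panel(),
                       spectral_signal = 0.6,
                       qtl_frac = 0.02,
                       fixed_effect_scale = 0.5,
                       replicate_noise_sd = 0.01,
                       batch_spectral_sd = 0.3,
                       outlier_frac = 0.01,
                       outlier_magnitude = 12,
                       n_generations = 3,
                       rng_seed = 1L) {
  if (n_cows < 4) {
    stop_spectrakin("`n_cows` must be at least 4.",
                    class = "spectrakin_config_error")
  }
  if (length(herd_sizes) != 2 || sum(herd_sizes) != n_cows) {
    stop_spectrakin("`herd_sizes` must be two counts summing to `n_cows`.",
                    class = "spectrakin_config_error")
  }
  traits <- tibble::as_tibble(traits)
  req <- c("trait", "mean", "sd", "h2_target", "hbatch_target")
  if (!all(req %in% names(traits))) {
    stop_spectrakin("`traits` must have columns ",
                    paste(req, collapse = ", "), ".",
                    class = "spectrakin_config_error")
  }
  bad <- traits$h2_target + traits$hbatch_target >= 1 |
    traits$h2_target < 0 | traits$hbatch_target < 0
  if (any(bad)) {
    stop_spectrakin(
      "h2_target + hbatch_target must be < 1 (violated for: ",
      paste(traits$trait[bad], collapse = ", "), ").",
      class = "spectrakin_config_error")
  }
  if (spectral_signal < 0 || spectral_signal > 1) {
    stop_spectrakin("`spectral_signal` must lie in [0, 1].",
                    class = "spectrakin_config_error")
  }
  structure(list(
    n_cows = as.integer(n_cows), n_snps = as.integer(n_snps),
    n_wavelengths = as.integer(n_wavelengths),
    n_batches = as.integer(n_batches),
    herd_sizes = as.integer(herd_sizes),
    n_dim_classes = as.integer(n_dim_classes),
    n_parity_classes = as.integer(n_parity_classes),
    traits = traits,
    spectral_signal = spectral_signal,
    qtl_frac = qtl_frac,
    fixed_effect_scale = fixed_effect_scale,
    replicate_noise_sd = replicate_noise_sd,
    batch_spectral_sd = batch_spectral_sd,
    outlier_frac = outlier_frac,
    outlier_magnitude = outlier_magnitude,
    n_generations = as.integer(n_generations),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Simulate a three-generation pedigree
#'
#' Builds a pedigree whose final generation holds the `n_cows` study cows.
#' Founders have unknown parents (coded 0) and every non-founder's sire and
#' dam appear earlier in the ordering, so the tabular relationship-matrix
#' recursion applies directly. With `n_generations = 1` only founders are
#' returned.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam` (0 = unknown),
#'   `generation`, `sex` and `is_study`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cows
  with_local_seed(config$rng_seed + 1L, {
    if (config$n_generations <= 1) {
      return(tibble::tibble(
        animal = seq_len(n), sire = 0L, dam = 0L,
        generation = 0L, sex = rep(c("M", "F"), length.out = n),
        is_study = TRUE))
    }
    n_sires <- max(2L, ceiling(n / 30))
    n0_dams <- max(2L, ceiling(n / 8))
    n1_dams <- max(2L, ceiling(n / 4))
    # generation 0: founders
    g0 <- tibble::tibble(
      animal = seq_len(n_sires + n0_dams), sire = 0L, dam = 0L,
      generation = 0L,
      sex = c(rep("M", n_sires), rep("F", n0_dams)),
      is_study = FALSE)
    g0_sires <- g0$animal[g0$sex == "M"]
    g0_dams <- g0$animal[g0$sex == "F"]
    # generation 1: parents of the study cows
    n1 <- n_sires + n1_dams
    off <- max(g0$animal)
    g1 <- tibble::tibble(
      animal = off + seq_len(n1),
      sire = sample(g0_sires, n1, replace = TRUE),
      dam = sample(g0_dams, n1, replace = TRUE),
      generation = 1L,
      sex = c(rep("M", n_sires), rep("F", n1_dams)),
      is_study = FALSE)
    g1_sires <- g1$animal[g1$sex == "M"]
    g1_dams <- g1$animal[g1$sex == "F"]
    # generation 2: study cows
    off <- max(g1$animal)
    g2 <- tibble::tibble(
      animal = off + seq_len(n),
      sire = sample(g1_sires, n, replace = TRUE),
      dam = sample(g1_dams, n, replace = TRUE),
      generation = 2L,
      sex = "F",
      is_study = TRUE)
    dplyr::bind_rows(g0, g1, g2)
  })
}

#' Simulate SNP genotypes by gene dropping through the pedigree
#'
#' Founder alleles are drawn with second-allele frequencies from
#' Uniform(0.05, 0.5) per SNP (so downstream MAF filtering is non-trivial);
#' offspring receive one allele from each parent, independently per SNP.
#' Dosages count the second allele (0/1/2).
#'
#' @param pedigree Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return A list of class `genotype_set`: `dosages` (animals x SNPs integer
#'   matrix, rownames = animal ids), `snp_meta` (tibble: `snp_id`, `chrom`,
#'   `pos`, `autosomal`, `freq2`), `sample_ids`, and `study_ids` (the
#'   genotyped study cows).
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  N <- nrow(pedigree)
  with_local_seed(config$rng_seed + 2L, {
    p2 <- runif(m, 0.05, 0.5)
    a1 <- matrix(0L, N, m)
    a2 <- matrix(0L, N, m)
    for (g in sort(unique(pedigree$generation))) {
      idx <- which(pedigree$generation == g)
      ng <- length(idx)
      founders <- pedigree$sire[idx] == 0L
      if (any(founders)) {
        fi <- idx[founders]
        nf <- length(fi)
        a1[fi, ] <- matrix(rbinom(nf * m, 1L, rep(p2, each = nf)), nf, m)
        a2[fi, ] <- matrix(rbinom(nf * m, 1L, rep(p2, each = nf)), nf, m)
      }
      if (any(!founders)) {
        ci <- idx[!founders]
        nc <- length(ci)
        si <- match(pedigree$sire[ci], pedigree$animal)
        di <- match(pedigree$dam[ci], pedigree$animal)
        pick_s <- matrix(runif(nc * m) < 0.5, nc, m)
        pick_d <- matrix(runif(nc * m) < 0.5, nc, m)
        a1[ci, ] <- ifelse(pick_s, a1[si, , drop = FALSE], a2[si, , drop = FALSE])
        a2[ci, ] <- ifelse(pick_d, a1[di, , drop = FALSE], a2[di, , drop = FALSE])
      }
    }
    dos <- a1 + a2
    storage.mode(dos) <- "integer"
    rownames(dos) <- as.character(pedigree$animal)
    snp_meta <- tibble::tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = sort(sample(1:29, m, replace = TRUE)),
      pos = seq_len(m) * 1000L,
      autosomal = TRUE,
      freq2 = p2)
    colnames(dos) <- snp_meta$snp_id
    structure(list(
      dosages = dos,
      snp_meta = snp_meta,
      sample_ids = as.character(pedigree$animal),
      study_ids = as.character(pedigree$animal[pedigree$is_study])
    ), class = "genotype_set")
  })
}

# Smooth random curve over the wavelength axis: a sum of Gaussian bumps.
smooth_curve <- function(p, n_bumps, width_range, amp_sd) {
  centers <- runif(n_bumps, 1, p)
  widths <- runif(n_bumps, width_range[1], width_range[2])
  amps <- rnorm(n_bumps, 0, amp_sd)
  x <- seq_len(p)
  out <- numeric(p)
  for (b in seq_len(n_bumps)) {
    out <- out + amps[b] * exp(-0.5 * ((x - centers[b]) / widths[b])^2)
  }
  out
}

#' Simulate phenotypes and replicate FTIR spectra
#'
#' Builds, for each trait, the layered phenotype
#' `y = mu + DIM class + parity class + breeding value + batch + residual`
#' with components scaled so that the additive share of (additive +
#' residual) variance hits `h2_target` and the batch share of total variance
#' hits `hbatch_target`, on each trait's clinical scale. Spectra are a
#' smooth baseline plus per-trait banded loadings times a latent
#' metabolite signal, a smooth batch-level drift, and channel noise; two
#' replicate spectra per cow differ only by replicate noise. The latent
#' signal carries `spectral_signal` of the non-batch phenotypic variance,
#' so batch effects are not recoverable from the metabolite bands (only,
#' partially, from the batch drift), which is what degrades batch-out and
#' herd-out prediction relative to tenfold CV.
#'
#' @param genotypes A `genotype_set` from [simulate_genotypes()].
#' @param pedigree The pedigree the genotypes were dropped through.
#' @param config A [sim_config()].
#' @return A list: `cow_table` (tibble with ids, herd, batch, DIM/parity and
#'   one column per trait), `spectra` (a [spectra_matrix] with two replicate
#'   rows per cow), and `truth` (a `sim_truth` list with the generating
#'   effects and realized variance components).
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cows
  p <- config$n_wavelengths
  traits <- config$traits
  nt <- nrow(traits)
  study <- genotypes$study_ids
  stopifnot(length(study) == n)

  with_local_seed(config$rng_seed + 3L, {
    # herd / batch / on-farm structure
    herd <- rep(1:2, times = config$herd_sizes)
    n_b2 <- max(1L, round(config$n_batches * config$herd_sizes[2] / n))
    n_b2 <- min(n_b2, config$n_batches - 1L)
    n_b1 <- config$n_batches - n_b2
    batch <- integer(n)
    batch[herd == 1] <- sample(rep_len(seq_len(n_b1), config$herd_sizes[1]))
    batch[herd == 2] <- n_b1 + sample(rep_len(seq_len(n_b2), config$herd_sizes[2]))
    dim_days <- round(runif(n, 5, 400))
    parity <- sample(1:6, n, replace = TRUE,
                     prob = c(0.35, 0.28, 0.18, 0.10, 0.06, 0.03))
    dimc <- dim_class(dim_days)
    parc <- parity_class(parity)

    dos_all <- genotypes$dosages
    study_rows <- match(study, rownames(dos_all))
    m <- ncol(dos_all)

    cow_table <- tibble::tibble(
      cow_id = sprintf("cow%05d", seq_len(n)),
      animal = as.integer(study),
      herd = herd, batch = batch,
      dim = dim_days, dim_class = dimc,
      parity = parity, parity_class = parc)

    wavenumbers <- seq(5011, 925, length.out = p)
    baseline <- 0.35 + smooth_curve(p, 6, c(p / 30, p / 8), 0.15)
    baseline <- pmin(pmax(baseline, 0.05), 0.9)

    loading_scale <- 0.05
    loadings <- matrix(0, p, nt)
    windows <- matrix(FALSE, p, nt)
    snp_effects <- vector("list", nt)
    bv <- matrix(0, n, nt)
    batch_eff <- matrix(0, config$n_batches, nt)
    dim_eff <- matrix(0, config$n_dim_classes, nt)
    par_eff <- matrix(0, config$n_parity_classes, nt)
    comp <- vector("list", nt)
    latent <- matrix(0, n, nt)

    for (t in seq_len(nt)) {
      h2 <- traits$h2_target[t]
      hb <- traits$hbatch_target[t]
      sdt <- traits$sd[t]
      s2_batch <- hb * sdt^2
      s2_a <- h2 * (1 - hb) * sdt^2
      s2_e <- (1 - h2) * (1 - hb) * sdt^2
      # breeding values: gene-dropped genotypes at planted QTL, scaled so the
      # realized study-cow variance equals the target exactly
      n_qtl <- max(2L, round(config$qtl_frac * m))
      qtl <- sample.int(m, n_qtl)
      beta <- rnorm(n_qtl)
      g_all <- as.numeric(dos_all[, qtl, drop = FALSE] %*% beta)
      g <- g_all[study_rows]
      if (s2_a > 0 && sd(g) > 0) {
        g <- (g - mean(g)) / sd(g) * sqrt(s2_a)
        beta_scaled <- beta / sd(g_all[study_rows]) * sqrt(s2_a)
      } else {
        g <- rep(0, n)
        beta_scaled <- rep(0, n_qtl)
      }
      eff <- numeric(m)
      eff[qtl] <- beta_scaled
      snp_effects[[t]] <- eff
      bv[, t] <- g
      be <- if (s2_batch > 0) rnorm(config$n_batches, 0, sqrt(s2_batch)) else
        rep(0, config$n_batches)
      # with few batches the raw draws realize a noisy variance; rescale so
      # the cow-level batch variance hits the target exactly
      if (s2_batch > 0 && sd(be[batch]) > 0) {
        be <- (be - mean(be[batch])) * sqrt(s2_batch) / sd(be[batch])
      }
      batch_eff[, t] <- be
      de <- seq(-1, 1, length.out = config$n_dim_classes) *
        config$fixed_effect_scale * sqrt(s2_e)
      pe <- seq(-1, 1, length.out = config$n_parity_classes) *
        config$fixed_effect_scale * sqrt(s2_e) * 0.6
      dim_eff[, t] <- de
      par_eff[, t] <- pe
      e <- rnorm(n, 0, sqrt(s2_e))
      y <- traits$mean[t] + de[dimc] + pe[parc] + g + be[batch] + e
      cow_table[[traits$trait[t]]] <- y
      comp[[t]] <- tibble::tibble(
        trait = traits$trait[t],
        sigma2_a = s2_a, sigma2_batch = s2_batch, sigma2_e = s2_e,
        h2 = if (s2_a + s2_e > 0) s2_a / (s2_a + s2_e) else 0,
        hbatch = if (s2_a + s2_batch + s2_e > 0)
          s2_batch / (s2_a + s2_batch + s2_e) else 0,
        realized_h2 = if (s2_a + s2_e > 0) var(g) / (var(g) + var(e)) else 0,
        realized_hbatch = if (s2_a + s2_batch + s2_e > 0)
          var(be[batch]) / (var(g) + var(be[batch]) + var(e)) else 0)
      # latent milk signal: the non-batch part of y, diluted to spectral_signal
      y_nb <- y - be[batch]
      s <- config$spectral_signal
      z <- if (sd(y_nb) > 0) (y_nb - mean(y_nb)) / sd(y_nb) else rep(0, n)
      latent[, t] <- sqrt(s) * z + sqrt(1 - s) * rnorm(n)
      # banded loadings: contiguous Gaussian windows
      n_win <- sample(10:30, 1)
      centers <- sample.int(p, n_win)
      widths <- runif(n_win, 2, 8)
      L <- numeric(p)
      for (w in seq_len(n_win)) {
        x <- seq_len(p)
        bump <- exp(-0.5 * ((x - centers[w]) / widths[w])^2)
        L <- L + rnorm(1, 0, 1) * bump
        windows[abs(x - centers[w]) <= 3 * widths[w], t] <- TRUE
      }
      L <- L / sqrt(sum(L^2)) * loading_scale
      loadings[, t] <- L
    }

    clean <- matrix(baseline, n, p, byrow = TRUE) +
      latent %*% t(loadings) / sqrt(nt)
    # smooth batch-level spectral drift (instrument/date nuisance)
    drift <- matrix(0, config$n_batches, p)
    for (b in seq_len(config$n_batches)) {
      drift[b, ] <- smooth_curve(p, 8, c(p / 40, p / 10),
                                 config$batch_spectral_sd * loading_scale)
    }
    clean <- clean + drift[batch, , drop = FALSE]

    # planted gross outliers
    n_out <- round(config$outlier_frac * n)
    outlier_ids <- character(0)
    if (n_out > 0) {
      chan_sd <- mean(apply(clean, 2, sd))
      out_rows <- sample.int(n, n_out)
      outlier_ids <- cow_table$cow_id[out_rows]
      for (i in out_rows) {
        clean[i, ] <- clean[i, ] +
          config$outlier_magnitude * chan_sd *
          abs(smooth_curve(p, 3, c(p / 20, p / 6), 1))
      }
    }

    # two replicates per cow
    vals <- clean[rep(seq_len(n), each = 2), , drop = FALSE] +
      matrix(rnorm(2 * n * p, 0, config$replicate_noise_sd), 2 * n, p)
    vals <- pmax(vals, 0.01)
    spectra <- as_spectra(vals, wavenumbers,
                          cow_id = rep(cow_table$cow_id, each = 2),
                          replicate = rep(1:2, n),
                          unit = "absorbance")

    truth <- structure(list(
      components = dplyr::bind_rows(comp),
      true_breeding_values = `dimnames<-`(bv, list(cow_table$cow_id, traits$trait)),
      true_snp_effects = setNames(snp_effects, traits$trait),
      true_batch_effects = `dimnames<-`(batch_eff, list(NULL, traits$trait)),
      true_dim_effects = `dimnames<-`(dim_eff, list(NULL, traits$trait)),
      true_parity_effects = `dimnames<-`(par_eff, list(NULL, traits$trait)),
      spectra_loadings = loadings,
      spectral_windows = windows,
      outlier_ids = outlier_ids
    ), class = "sim_truth")

    list(cow_table = cow_table, spectra = spectra, truth = truth)
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_phenotypes()] under one
#' configuration.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `pedigree`, `genotypes`, `cow_table`,
#'   `spectra` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  phe <- simulate_phenotypes(gen, ped, config)
  list(config = config, pedigree = ped, genotypes = gen,
       cow_table = phe$cow_table, spectra = phe$spectra, truth = phe$truth)
}
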