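#' MCMC chain configuration
#'
#' Defaults are a desk-scale chain (50,000 cycles, 10,000 burn-in, thinning
#' of 5); the study-scale setting of 500,000 cycles with a 100,000 burn-in
#' and the same thinning is available by configuration. Stored-sample count
#' is exactly `(n_iter - burn_in) / thin`.
#'
#' @param n_iter Total Gibbs cycles.
#' @param burn_in Discarded initial cycles; must be `< n_iter`.
#' @param thin Keep every `thin`-th cycle; `>= 1`.
#' @param rng_seed Integer seed.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iter = 50000, burn_in = 10000, thin = 5,
                         rng_seed = 1L) {
  if (burn_in >= n_iter || thin < 1) {
    stop_spectrakin("Need burn_in < n_iter and thin >= 1.",
                    class = "spectrakin_config_error")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), rng_seed = as.integer(rng_seed)),
            class = "chain_config")
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)` — the batch variance is excluded
#' from the denominator, exactly as in the animal-model parameterization
#' used throughout this package. Vectorized over posterior samples; the
#' posterior summary is the mean of per-sample ratios.
#'
#' @param sigma2_a Additive-genetic variance(s).
#' @param sigma2_e Residual variance(s).
#' @return Heritability value(s) in \[0, 1\].
#' @export
heritability <- function(sigma2_a, sigma2_e) {
  if (any(sigma2_a < 0 | sigma2_e < 0)) {
    stop_spectrakin("Variances must be non-negative.",
                    class = "spectrakin_parameter_error")
  }
  tot <- sigma2_a + sigma2_e
  if (any(tot == 0)) {
    stop_spectrakin("sigma2_a + sigma2_e is zero: heritability undefined.",
                    class = "spectrakin_undefined_error")
  }
  sigma2_a / tot
}

#' Batch incidence from variance components
#'
#' `h_batch = sigma2_batch / (sigma2_a + sigma2_batch + sigma2_e)`: the
#' batch share of total phenotypic variance.
#'
#' @param sigma2_a,sigma2_batch,sigma2_e Variance components.
#' @return Batch incidence value(s) in \[0, 1\].
#' @export
batch_incidence <- function(sigma2_a, sigma2_batch, sigma2_e) {
  if (any(sigma2_a < 0 | sigma2_batch < 0 | sigma2_e < 0)) {
    stop_spectrakin("Variances must be non-negative.",
                    class = "spectrakin_parameter_error")
  }
  tot <- sigma2_a + sigma2_batch + sigma2_e
  if (any(tot == 0)) {
    stop_spectrakin("Total variance is zero: batch incidence undefined.",
                    class = "spectrakin_undefined_error")
  }
  sigma2_batch / tot
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac1` of a stored chain against the
#' mean of the last `frac2`, with variances estimated by the spectral
#' density at frequency zero (autoregressive estimator), and returns the
#' z-score and its two-sided p-value. Small p indicates non-convergence.
#'
#' @param x Numeric vector of stored MCMC samples (at least 100).
#' @param frac1,frac2 Early and late chain fractions (classical 0.1 / 0.5).
#' @return A list with `z` and `p.value`.
#' @export
geweke_diagnostic <- function(x, frac1 = 0.1, frac2 = 0.5) {
  x <- as.numeric(x)
  if (length(x) < 100) {
    stop_spectrakin("Need at least 100 stored samples for the Geweke test.",
                    class = "spectrakin_insufficient_samples_error")
  }
  if (sd(x) == 0) {
    stop_spectrakin("Chain is constant: Geweke diagnostic is degenerate.",
                    class = "spectrakin_degenerate_chain_error")
  }
  n <- length(x)
  x1 <- x[seq_len(floor(frac1 * n))]
  x2 <- x[(n - floor(frac2 * n) + 1):n]
  spec0 <- function(v) {
    if (sd(v) == 0) return(0)
    fit <- tryCatch(ar(v, aic = TRUE, order.max = min(20, length(v) - 1)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  v1 <- spec0(x1) / length(x1)
  v2 <- spec0(x2) / length(x2)
  if (v1 + v2 == 0) {
    stop_spectrakin("Zero spectral variance: Geweke diagnostic is degenerate.",
                    class = "spectrakin_degenerate_chain_error")
  }
  z <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  list(z = z, p.value = 2 * pnorm(-abs(z)))
}

#' Gibbs sampler for the single-step GBLUP animal model
#'
#' Fits `y = X b + W h + Z a + e` with `a ~ N(0, H sigma2_a)`,
#' `h ~ N(0, I sigma2_batch)`, `e ~ N(0, I sigma2_e)` by blocked Gibbs
#' sampling: location effects from their full conditionals given the
#' variances (single-site with residual updating), variances from
#' scaled-inverse-chi-square full conditionals (flat prior on fixed
#' effects). The fixed-effect design holds an intercept plus days-in-milk
#' and parity class dummies; the pedigree-genomic structure enters through
#' `H^-1` from a [kinship_bundle()].
#'
#' @param data Cow table with the trait column plus `animal`, `batch`,
#'   `dim_class`, `parity_class`.
#' @param trait Name of the trait column to analyse.
#' @param kinship A [kinship_bundle()] (or a list with `Hinv` and
#'   `id_order`) covering every animal in `data` plus ancestors.
#' @param chain A [chain_config()].
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-square
#'   priors (default 4).
#' @param prior_split Fractions of the phenotypic variance used as prior
#'   scales for (additive, batch, residual); default `c(0.25, 0.25, 0.5)`.
#' @param fix_sigma2 Length-3 numeric `(a, batch, e)`; non-`NA` entries are
#'   held fixed instead of sampled (used for closed-form oracle checks).
#' @param use_batch Include the random batch term (default `TRUE`).
#' @return An object of class `ssgblup_fit` with posterior samples of the
#'   variance components, heritability and batch incidence, fixed-effect
#'   samples, posterior-mean breeding values, Geweke diagnostics and a
#'   convergence flag.
#' @export
animal_model_gibbs <- function(data, trait, kinship,
                               chain = chain_config(),
                               prior_df = 4,
                               prior_split = c(0.25, 0.25, 0.5),
                               fix_sigma2 = c(NA, NA, NA),
                               use_batch = TRUE) {
  stopifnot(trait %in% names(data))
  y <- data[[trait]]
  if (anyNA(y)) {
    stop_spectrakin("Trait has missing values; complete cases required.",
                    class = "spectrakin_data_error")
  }
  id_order <- kinship$id_order %||% rownames(kinship$Hinv)
  aidx <- match(as.character(data$animal), id_order)
  if (anyNA(aidx)) {
    stop_spectrakin("Some animals in `data` are missing from the kinship bundle.",
                    class = "spectrakin_data_error")
  }
  df <- data.frame(dim_class = factor(data$dim_class),
                   parity_class = factor(data$parity_class))
  terms <- c("dim_class", "parity_class")[
    c(nlevels(df$dim_class) > 1, nlevels(df$parity_class) > 1)]
  fml <- if (length(terms) > 0) {
    stats::reformulate(terms)
  } else ~1
  X <- stats::model.matrix(fml, data = df)
  if (use_batch) {
    bf <- factor(data$batch)
    bidx <- as.integer(bf) - 1L
    n_batch <- nlevels(bf)
  } else {
    bidx <- integer(length(y))
    n_batch <- 0L
  }
  vy <- var(y)
  S <- prior_split * vy  # (a, batch, e) prior scales
  init <- ifelse(is.na(fix_sigma2), S, fix_sigma2)
  init[init <= 0] <- vy * 1e-3

  res <- with_local_seed(chain$rng_seed, {
    .animal_gibbs(as.numeric(y), X, bidx, n_batch, aidx - 1L,
                  kinship$Hinv,
                  chain$n_iter, chain$burn_in, chain$thin,
                  prior_df, S[1], prior_df, S[2], prior_df, S[3],
                  as.numeric(fix_sigma2), as.numeric(init))
  })

  vs <- res$var_samples
  samples <- tibble::tibble(
    sample = seq_len(nrow(vs)),
    sigma2_a = vs[, 1],
    sigma2_batch = vs[, 2],
    sigma2_e = vs[, 3])
  samples$h2 <- heritability(samples$sigma2_a, samples$sigma2_e)
  samples$hbatch <- if (use_batch) {
    batch_incidence(samples$sigma2_a, samples$sigma2_batch, samples$sigma2_e)
  } else NA_real_
  pars <- c("sigma2_a", if (use_batch) "sigma2_batch", "sigma2_e",
            "h2", if (use_batch) "hbatch")
  geweke <- purrr::map_dfr(pars, function(pp) {
    gw <- if (sd(samples[[pp]]) == 0) list(z = 0, p.value = 1) else
      geweke_diagnostic(samples[[pp]])
    tibble::tibble(term = pp, geweke_z = gw$z, geweke_p = gw$p.value)
  })
  summary_tbl <- tibble::tibble(
    term = pars,
    estimate = vapply(pars, function(pp) mean(samples[[pp]]), numeric(1)),
    std.error = vapply(pars, function(pp) sd(samples[[pp]]), numeric(1))) |>
    dplyr::left_join(geweke, by = "term")
  conv <- geweke$geweke_p[geweke$term == "sigma2_a"] > 0.05
  a_mean <- setNames(as.numeric(res$a_mean), id_order)
  structure(list(trait = trait,
                 samples = samples,
                 summary = summary_tbl,
                 b_samples = res$b_samples,
                 b_names = colnames(X),
                 a_mean = a_mean,
                 h_mean = if (use_batch) setNames(res$h_mean, levels(factor(data$batch))) else NULL,
                 chain = chain,
                 n_stored = res$n_stored,
                 converged = isTRUE(conv)),
            class = "ssgblup_fit")
}

#' @export
print.ssgblup_fit <- function(x, ...) {
  cat(sprintf("<ssgblup_fit> trait '%s': %d stored samples%s\n",
              x$trait, x$n_stored,
              if (x$converged) "" else " (Geweke flagged non-convergence)"))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.spectrakin
#' @export
tidy.ssgblup_fit <- function(x, ...) x$summary

#' @rdname tidy.spectrakin
#' @export
glance.ssgblup_fit <- function(x, ...) {
  s <- x$summary
  pick <- function(term, col) {
    v <- s[[col]][s$term == term]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    trait = x$trait,
    h2 = pick("h2", "estimate"), h2_sd = pick("h2", "std.error"),
    hbatch = pick("hbatch", "estimate"), hbatch_sd = pick("hbatch", "std.error"),
    sigma2_a = pick("sigma2_a", "estimate"),
    sigma2_batch = pick("sigma2_batch", "estimate"),
    sigma2_e = pick("sigma2_e", "estimate"),
    n_stored = x$n_stored, converged = x$converged)
}
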