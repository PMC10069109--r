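#' Beta-prior shapes for the BayesB inclusion probability
#'
#' Records the quantity `pi0 * (1 - pi0) / (counts + 1)` — the published
#' parameterization of the beta prior's first shape, which equals the
#' variance of a Beta with mean `pi0` and concentration `counts + 1` —
#' alongside the conventional mean/concentration shapes
#' `(pi0 * counts, (1 - pi0) * counts)` used by the sampler. Both are
#' written to the run manifest.
#'
#' @param pi0 Prior mean proportion of nonzero effects, in (0, 1).
#' @param counts Concentration of the beta prior (>= 0).
#' @return A list: `shape1_printed`, `p0`, `shape_in`, `shape_out`.
#' @export
beta_prior_shapes <- function(pi0 = 0.5, counts = 10) {
  if (pi0 <= 0 || pi0 >= 1 || counts < 0) {
    stop_spectrakin("Need pi0 in (0, 1) and counts >= 0.",
                    class = "spectrakin_parameter_error")
  }
  list(shape1_printed = pi0 * (1 - pi0) / (counts + 1),
       p0 = pi0,
       shape_in = pi0 * counts,
       shape_out = (1 - pi0) * counts)
}

#' Scale of the BayesB effect-variance prior
#'
#' `S_B = var(y) * VP * (df + 2) / MS_x / pi`, where `MS_x` is the sum of
#' the variances of the predictor columns and `VP` the variance partition
#' attributed to the linear predictors. With this scale the prior mode of a
#' slab variance is `S_B / (df + 2)`, so the expected predictor-explained
#' variance is `VP * var(y)`.
#'
#' @param var_y Phenotypic variance of the training response.
#' @param VP Variance partition in (0, 1\]; default 0.5.
#' @param df Slab degrees of freedom; default 5.
#' @param MSx Sum of predictor column variances (> 0).
#' @param pi Proportion of nonzero effects (> 0).
#' @return The scalar prior scale.
#' @export
compute_SB <- function(var_y, VP = 0.5, df = 5, MSx, pi = 0.5) {
  if (MSx <= 0 || pi <= 0) {
    stop_spectrakin("Degenerate prior: need MSx > 0 and pi > 0.",
                    class = "spectrakin_parameter_error")
  }
  var_y * VP * (df + 2) / MSx / pi
}

#' BayesB prior configuration
#'
#' Defaults mirror the BGLR-style defaults: scaled-t slab with 5 degrees of
#' freedom, prior inclusion proportion 0.5 with concentration 10, variance
#' partition 0.5 for the linear predictors and 0.5 for the residual.
#'
#' @param df_u Slab degrees of freedom.
#' @param pi0 Prior mean inclusion proportion.
#' @param counts Beta-prior concentration.
#' @param VP Variance partition for the predictors.
#' @param R2_resid Residual variance partition.
#' @param df_e Residual degrees of freedom.
#' @return A list of class `bayesb_prior`.
#' @export
bayesb_prior <- function(df_u = 5, pi0 = 0.5, counts = 10,
                         VP = 0.5, R2_resid = 0.5, df_e = 5) {
  if (VP <= 0 || VP > 1) {
    stop_spectrakin("VP must lie in (0, 1].",
                    class = "spectrakin_parameter_error")
  }
  shapes <- beta_prior_shapes(pi0, counts)
  structure(list(df_u = df_u, pi0 = pi0, counts = counts, VP = VP,
                 R2_resid = R2_resid, df_e = df_e, shapes = shapes),
            class = "bayesb_prior")
}

# One-hot on-farm covariate block (flat prior): DIM and parity class
# dummies, reference level absorbed by the intercept.
onfarm_design <- function(onfarm) {
  df <- data.frame(dim_class = factor(onfarm$dim_class),
                   parity_class = factor(onfarm$parity_class))
  terms <- c("dim_class", "parity_class")[
    c(nlevels(df$dim_class) > 1, nlevels(df$parity_class) > 1)]
  if (length(terms) == 0) {
    return(matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(stats::reformulate(terms), data = df)
}

#' BayesB regression over heterogeneous predictor blocks
#'
#' Fits the mixture-prior whole-spectrum/whole-genome regression: each
#' penalized predictor's effect is exactly zero with probability `1 - pi`
#' and scaled-t otherwise (hierarchically normal with its own
#' scaled-inverse-chi-square variance), one mixture proportion `pi` shared
#' across the FTIR and SNP blocks. On-farm covariates (DIM and parity
#' classes) enter as an unpenalized one-hot block with a flat prior.
#' Penalized columns are standardized with training statistics, which are
#' stored for prediction.
#'
#' @param y Numeric response (training trait values).
#' @param ftir FTIR predictor matrix (rows aligned with `y`).
#' @param snp Optional SNP dosage matrix.
#' @param onfarm Optional data frame with `dim_class` and `parity_class`.
#' @param prior A [bayesb_prior()].
#' @param chain A [chain_config()]; desk default 20,000 cycles, 5,000
#'   burn-in, thinning 5.
#' @param fix_pi Optional fixed inclusion proportion (disables the beta
#'   update); `fix_pi = 1` with `fix_effect_variance` gives the ridge
#'   limit.
#' @param fix_effect_variance Optional common fixed slab variance.
#' @param fix_sigma2_e Optional fixed residual variance.
#' @return An object of class `bayesb_fit` with posterior-mean effects,
#'   inclusion frequencies, the fixed-block coefficients, standardization
#'   statistics and a run manifest.
#' @export
bayesb <- function(y, ftir, snp = NULL, onfarm = NULL,
                   prior = bayesb_prior(),
                   chain = chain_config(20000, 5000, 5),
                   fix_pi = NULL, fix_effect_variance = NULL,
                   fix_sigma2_e = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2 || sd(y) == 0) {
    stop_spectrakin("Need n >= 2 and non-constant y.",
                    class = "spectrakin_data_error")
  }
  blocks <- list(ftir = as.matrix(ftir))
  if (!is.null(snp)) blocks$snp <- as.matrix(snp)
  for (b in names(blocks)) {
    if (nrow(blocks[[b]]) != n) {
      stop_spectrakin("Block '", b, "' rows do not match length(y).",
                      class = "spectrakin_alignment_error")
    }
    if (is.null(colnames(blocks[[b]]))) {
      colnames(blocks[[b]]) <- sprintf("%s%04d", b, seq_len(ncol(blocks[[b]])))
    }
  }
  Xp <- do.call(cbind, blocks)
  block_id <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  centers <- colMeans(Xp)
  scales <- apply(Xp, 2, sd)
  scales[scales == 0] <- 1
  Xp <- sweep(sweep(Xp, 2, centers), 2, scales, "/")
  Xf <- if (is.null(onfarm)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    onfarm_design(onfarm)
  }

  vy <- var(y)
  MSx <- sum(apply(Xp, 2, var))
  pi0 <- fix_pi %||% prior$pi0
  S_B <- compute_SB(vy, prior$VP, prior$df_u, MSx, pi0)
  S_e <- vy * prior$R2_resid * (prior$df_e + 2)

  res <- with_local_seed(chain$rng_seed, {
    .bayesb_gibbs(y, Xf, Xp,
                  chain$n_iter, chain$burn_in, chain$thin,
                  prior$df_u, S_B, prior$df_e, S_e,
                  max(prior$shapes$shape_in, 1e-8),
                  max(prior$shapes$shape_out, 1e-8),
                  pi0, is.null(fix_pi),
                  fix_effect_variance %||% NA_real_,
                  fix_sigma2_e %||% NA_real_)
  })

  manifest <- list(
    prior = unclass(prior),
    beta_shapes = prior$shapes,
    S_B = S_B, S_e = S_e, MSx = MSx, var_y = vy,
    n = n, p = ncol(Xp),
    blocks = table(block_id),
    chain = unclass(chain),
    fixed_pi = fix_pi, fixed_effect_variance = fix_effect_variance)

  structure(list(
    effects = setNames(as.numeric(res$effect_mean), colnames(Xp)),
    inclusion_freq = setNames(as.numeric(res$inclusion_freq), colnames(Xp)),
    block = setNames(block_id, colnames(Xp)),
    fixed_coef = setNames(as.numeric(res$fixed_mean), colnames(Xf)),
    fixed_names = colnames(Xf),
    centers = centers, scales = scales,
    pi_mean = mean(res$pi_chain),
    sigma2_e_mean = mean(res$sigma2_e_chain),
    pi_chain = as.numeric(res$pi_chain),
    sigma2_e_chain = as.numeric(res$sigma2_e_chain),
    n_stored = res$n_stored,
    manifest = manifest
  ), class = "bayesb_fit")
}

#' Predict from a BayesB fit
#'
#' Applies the training-fold standardization to the new predictor blocks
#' and returns the posterior-mean linear predictor
#' `intercept + covariates + X_new %*% effects`.
#'
#' @param object A [bayesb()] fit.
#' @param ftir,snp,onfarm New-data blocks matching the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.bayesb_fit <- function(object, ftir, snp = NULL, onfarm = NULL, ...) {
  blocks <- list(ftir = as.matrix(ftir))
  if (!is.null(snp)) blocks$snp <- as.matrix(snp)
  Xp <- do.call(cbind, blocks)
  if (ncol(Xp) != length(object$effects)) {
    stop_spectrakin(
      sprintf("Predictor columns (%d) do not match the training blocks (%d).",
              ncol(Xp), length(object$effects)),
      class = "spectrakin_alignment_error")
  }
  Xp <- sweep(sweep(Xp, 2, object$centers), 2, object$scales, "/")
  Xf <- if (is.null(onfarm)) {
    matrix(1, nrow(Xp), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    onfarm_design(onfarm)
  }
  keep <- intersect(colnames(Xf), object$fixed_names)
  eta <- as.numeric(Xp %*% object$effects)
  eta <- eta + as.numeric(Xf[, keep, drop = FALSE] %*%
                            object$fixed_coef[keep])
  eta
}

#' @export
print.bayesb_fit <- function(x, ...) {
  cat(sprintf(
    "<bayesb_fit> %d predictors (%s), pi = %.3f, sigma2_e = %.4g\n",
    length(x$effects),
    paste(sprintf("%s: %d", names(x$manifest$blocks),
                  as.integer(x$manifest$blocks)), collapse = ", "),
    x$pi_mean, x$sigma2_e_mean))
  invisible(x)
}

#' Tidy and glance methods for spectrakin fits
#'
#' `tidy()` returns per-term tables (posterior effects for BayesB, variance
#' components for the animal model, variable importances for GBM);
#' `glance()` returns one-row model summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.spectrakin
NULL

#' @rdname tidy.spectrakin
#' @export
tidy.bayesb_fit <- function(x, ...) {
  tibble::tibble(term = names(x$effects),
                 block = unname(x$block),
                 estimate = unname(x$effects),
                 inclusion = unname(x$inclusion_freq))
}

#' @rdname tidy.spectrakin
#' @export
glance.bayesb_fit <- function(x, ...) {
  tibble::tibble(n = x$manifest$n, p = x$manifest$p,
                 pi = x$pi_mean, sigma2_e = x$sigma2_e_mean,
                 S_B = x$manifest$S_B, n_stored = x$n_stored)
}
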