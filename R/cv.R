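#' Tenfold random cross-validation assignment
#'
#' Randomly partitions the cows into ten non-overlapping folds of
#' approximately equal size (within one cow). Each fold is validated
#' exactly once; the same assignment is reused by both methods and all four
#' predictor models.
#'
#' @param cow_ids Character vector of cow ids.
#' @param seed Integer seed.
#' @param n_folds Number of folds (default 10).
#' @return A `cv_scheme` tibble: `scheme`, `replicate`, list-columns
#'   `train` and `validation`.
#' @export
cv_tenfold <- function(cow_ids, seed = 1L, n_folds = 10) {
  n <- length(cow_ids)
  if (n < n_folds) {
    stop_spectrakin("Need at least as many cows as folds.",
                    class = "spectrakin_config_error")
  }
  fold <- with_local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  out <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tibble::tibble(scheme = "tenfold", replicate = f,
                   train = list(cow_ids[fold != f]),
                   validation = list(cow_ids[fold == f]))
  })
  class(out) <- c("cv_scheme", class(out))
  out
}

#' Batch-out cross-validation assignment by genomic distance
#'
#' Summarizes each batch by the mean genomic-relationship profile of its
#' cows (the average of their rows of G), computes Euclidean distances
#' between batch profiles, ranks batches by their mean distance to all
#' other batches, and deals them round-robin into `n_replicates` validation
#' sets (most distant batches spread across replicates). Every batch is
#' validated exactly once; with 16 batches and 5 replicates the validation
#' sets hold 4, 3, 3, 3 and 3 batches.
#'
#' @param cow_ids Cow ids (must index rows of `G`).
#' @param batches Batch label per cow.
#' @param G Genomic relationship matrix with cow-id dimnames covering
#'   `cow_ids`.
#' @param n_replicates Number of replicates (default 5).
#' @return A `cv_scheme` tibble as in [cv_tenfold()], with the validated
#'   batches in a `validation_batches` list-column.
#' @export
cv_batch_out <- function(cow_ids, batches, G, n_replicates = 5) {
  stopifnot(length(cow_ids) == length(batches))
  ub <- sort(unique(batches))
  if (length(ub) < n_replicates) {
    stop_spectrakin("Need at least as many batches as replicates.",
                    class = "spectrakin_config_error")
  }
  idx <- match(cow_ids, rownames(G))
  if (anyNA(idx)) {
    stop_spectrakin("Some cows are missing from G: batch profiles undefined.",
                    class = "spectrakin_profile_error")
  }
  profiles <- t(vapply(ub, function(b) {
    colMeans(G[idx[batches == b], , drop = FALSE])
  }, numeric(ncol(G))))
  D <- as.matrix(stats::dist(profiles))
  mean_dist <- rowSums(D) / (length(ub) - 1)
  ranked <- ub[order(-mean_dist, ub)]
  assign_rep <- rep_len(seq_len(n_replicates), length(ub))
  out <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    vb <- ranked[assign_rep == r]
    vidx <- batches %in% vb
    tibble::tibble(scheme = "batch_out", replicate = r,
                   train = list(cow_ids[!vidx]),
                   validation = list(cow_ids[vidx]),
                   validation_batches = list(vb))
  })
  class(out) <- c("cv_scheme", class(out))
  out
}

#' Herd-out cross-validation assignment
#'
#' Emits both directions: train on herd 1 / validate herd 2, and the
#' reverse. Requires exactly two herds.
#'
#' @param cow_ids Cow ids.
#' @param herds Herd label per cow (exactly two distinct values).
#' @return A `cv_scheme` tibble with two replicates.
#' @export
cv_herd_out <- function(cow_ids, herds) {
  uh <- sort(unique(herds))
  if (length(uh) != 2) {
    stop_spectrakin("Herd-out validation requires exactly 2 herds (got ",
                    length(uh), ").", class = "spectrakin_config_error")
  }
  out <- purrr::map_dfr(1:2, function(r) {
    vh <- uh[if (r == 1) 2 else 1]
    tibble::tibble(scheme = "herd_out", replicate = r,
                   train = list(cow_ids[herds != vh]),
                   validation = list(cow_ids[herds == vh]))
  })
  class(out) <- c("cv_scheme", class(out))
  out
}

#' Predictive ability (squared Pearson correlation)
#'
#' The coefficient of determination between observed and predicted
#' phenotypes, defined as the squared Pearson correlation (bias is
#' reported separately by the calibration slope).
#'
#' @param y_obs,y_pred Numeric vectors of equal length >= 3.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 3) {
    stop_spectrakin("Need equal-length vectors of length >= 3.",
                    class = "spectrakin_data_error")
  }
  if (sd(y_obs) == 0 || sd(y_pred) == 0) {
    stop_spectrakin("Zero variance input: R-squared undefined.",
                    class = "spectrakin_undefined_error")
  }
  cor(y_obs, y_pred)^2
}

#' Root mean squared error
#'
#' `sqrt(sum((y - yhat)^2) / n)`.
#'
#' @param y_obs,y_pred Numeric vectors of equal length.
#' @return RMSE in the units of the trait.
#' @export
rmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 1) {
    stop_spectrakin("Need equal-length non-empty vectors.",
                    class = "spectrakin_data_error")
  }
  sqrt(mean((y_obs - y_pred)^2))
}

#' Calibration slope (bias)
#'
#' OLS slope of the observed values regressed on the predicted values;
#' 1 indicates unbiased predictions, values below 1 inflated and above 1
#' deflated predictions.
#'
#' @param y_obs,y_pred Numeric vectors; `var(y_pred) > 0`.
#' @return The regression slope.
#' @export
calibration_slope <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    stop_spectrakin("Length mismatch.", class = "spectrakin_data_error")
  }
  if (sd(y_pred) == 0) {
    stop_spectrakin("Zero-variance predictions: slope undefined.",
                    class = "spectrakin_undefined_error")
  }
  unname(coef(lm(y_obs ~ y_pred))[2])
}

#' Relative difference in predictive ability
#'
#' `RD = (r_m - r_M1) / r_M1 * 100`: the signed percent gain of model `m`
#' over the FTIR-only baseline.
#'
#' @param r_m Predictive ability of the richer model.
#' @param r_M1 Predictive ability of the baseline (must be > 0).
#' @return Percent relative difference.
#' @export
relative_difference <- function(r_m, r_M1) {
  if (any(r_M1 <= 0)) {
    stop_spectrakin("Baseline predictive ability must be positive.",
                    class = "spectrakin_undefined_error")
  }
  (r_m - r_M1) / r_M1 * 100
}

#' Regression of relative differences on heritability
#'
#' OLS of per-trait relative differences (M4 vs M1) on the per-trait
#' heritability estimates, summarizing how much of the gain from adding
#' genomic and on-farm data tracks genetic control of the trait.
#'
#' @param rd_per_trait Numeric vector of RD values (>= 3 traits).
#' @param h2_per_trait Matching heritability estimates.
#' @return A tibble: `slope`, `intercept`, `r2`.
#' @export
rd_vs_h2_regression <- function(rd_per_trait, h2_per_trait) {
  if (length(rd_per_trait) != length(h2_per_trait) ||
      length(rd_per_trait) < 3) {
    stop_spectrakin("Need >= 3 matching (RD, h2) pairs.",
                    class = "spectrakin_data_error")
  }
  fit <- lm(rd_per_trait ~ h2_per_trait)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = summary(fit)$r.squared)
}

#' Wavelength-trait Pearson correlations
#'
#' Pearson correlation between each selected wavelength's absorbance and
#' each trait, over complete cases. Zero-variance columns are skipped with
#' a warning.
#'
#' @param spectra Matrix of spectral values (cows x wavelengths, named
#'   columns) — typically a subset of [spectra_values()] at the
#'   significant wavelengths.
#' @param traits Data frame of trait phenotypes aligned with the rows.
#' @return A tibble `wavelength`, `trait`, `correlation`.
#' @export
wavelength_trait_correlations <- function(spectra, traits) {
  spectra <- as.matrix(spectra)
  keep <- apply(spectra, 2, sd) > 0
  if (any(!keep)) {
    rlang::warn(paste0("Skipping zero-variance wavelengths: ",
                       paste(colnames(spectra)[!keep], collapse = ", ")))
    spectra <- spectra[, keep, drop = FALSE]
  }
  purrr::map_dfr(colnames(spectra), function(w) {
    purrr::map_dfr(names(traits), function(tr) {
      y <- traits[[tr]]
      if (sd(y) == 0) return(NULL)
      tibble::tibble(wavelength = w, trait = tr,
                     correlation = cor(spectra[, w], y,
                                       use = "complete.obs"))
    })
  })
}

# Predictor model composition: which blocks enter M1..M4.
model_blocks <- function(model) {
  switch(model,
         M1 = list(onfarm = FALSE, snp = FALSE),
         M2 = list(onfarm = TRUE, snp = FALSE),
         M3 = list(onfarm = FALSE, snp = TRUE),
         M4 = list(onfarm = TRUE, snp = TRUE),
         stop_spectrakin("Unknown model '", model, "'; use M1..M4.",
                         class = "spectrakin_config_error"))
}

# Fit + predict one train/validation split with one method and model.
fit_one_cell <- function(method, model, trait, cow_table, spectra_mat,
                         snp_mat, train_ids, valid_ids,
                         bayesb_chain, gbm_space) {
  mb <- model_blocks(model)
  tr <- match(train_ids, cow_table$cow_id)
  va <- match(valid_ids, cow_table$cow_id)
  y_tr <- cow_table[[trait]][tr]
  y_va <- cow_table[[trait]][va]
  F_tr <- spectra_mat[train_ids, , drop = FALSE]
  F_va <- spectra_mat[valid_ids, , drop = FALSE]
  S_tr <- if (mb$snp) snp_mat[as.character(cow_table$animal[tr]), , drop = FALSE] else NULL
  S_va <- if (mb$snp) snp_mat[as.character(cow_table$animal[va]), , drop = FALSE] else NULL
  if (method == "BayesB") {
    of_tr <- if (mb$onfarm) cow_table[tr, c("dim_class", "parity_class")] else NULL
    of_va <- if (mb$onfarm) cow_table[va, c("dim_class", "parity_class")] else NULL
    fit <- bayesb(y_tr, ftir = F_tr, snp = S_tr, onfarm = of_tr,
                  chain = bayesb_chain)
    pred <- predict(fit, ftir = F_va, snp = S_va, onfarm = of_va)
  } else if (method == "GBM") {
    # on-farm covariates as integer-coded ordinal features
    X_tr <- F_tr
    X_va <- F_va
    if (mb$onfarm) {
      X_tr <- cbind(X_tr, dim_class = cow_table$dim_class[tr],
                    parity_class = cow_table$parity_class[tr])
      X_va <- cbind(X_va, dim_class = cow_table$dim_class[va],
                    parity_class = cow_table$parity_class[va])
    }
    if (mb$snp) {
      X_tr <- cbind(X_tr, S_tr)
      X_va <- cbind(X_va, S_va)
    }
    fit <- gbm_tune(X_tr, y_tr, space = gbm_space)
    pred <- predict(fit, X_va)
  } else {
    stop_spectrakin("Unknown method '", method, "'.",
                    class = "spectrakin_config_error")
  }
  tibble::tibble(
    trait = trait, method = method, model = model,
    n_valid = length(valid_ids),
    r2 = if (sd(pred) == 0) 0 else r_squared(y_va, pred),
    rmse = rmse(y_va, pred),
    slope = if (sd(pred) == 0) NA_real_ else calibration_slope(y_va, pred))
}

#' Run the full prediction factorial
#'
#' Evaluates every requested method (BayesB, GBM), predictor model
#' (M1-M4), cross-validation scheme and trait over fixed train/validation
#' splits: the same folds are consumed by both methods and all models
#' within a scheme. Returns one row per scheme x replicate x method x
#' model x trait.
#'
#' @param bundle Aligned data bundle from [load_and_align()] (or a list
#'   with `cow_table`, `spectra_mat`, `snp_mat`, `G`).
#' @param traits Trait columns to predict.
#' @param methods Subset of `c("BayesB", "GBM")`.
#' @param models Subset of `c("M1", "M2", "M3", "M4")`.
#' @param schemes Subset of `c("tenfold", "batch_out", "herd_out")`, or a
#'   pre-built named list of `cv_scheme` tibbles.
#' @param seed Master seed for the fold assignments and samplers.
#' @param bayesb_chain A [chain_config()] for the BayesB fits.
#' @param gbm_space A [gbm_search_space()] for the GBM tuning.
#' @return A tibble of per-replicate results (class
#'   `spectrakin_experiment`).
#' @export
run_experiment <- function(bundle,
                           traits,
                           methods = c("BayesB", "GBM"),
                           models = c("M1", "M2", "M3", "M4"),
                           schemes = c("tenfold", "batch_out", "herd_out"),
                           seed = 1L,
                           bayesb_chain = chain_config(3000, 1000, 2,
                                                       rng_seed = seed),
                           gbm_space = gbm_search_space(max_models = 10,
                                                        rng_seed = seed)) {
  ct <- bundle$cow_table
  spectra_mat <- bundle$spectra_mat
  snp_mat <- bundle$snp_mat
  if (is.character(schemes)) {
    schemes <- setNames(lapply(schemes, function(s) {
      switch(s,
             tenfold = cv_tenfold(ct$cow_id, seed = seed),
             batch_out = cv_batch_out(ct$cow_id, ct$batch,
                                      cow_relabel_G(bundle), n_replicates = 5),
             herd_out = cv_herd_out(ct$cow_id, ct$herd),
             stop_spectrakin("Unknown scheme '", s, "'.",
                             class = "spectrakin_config_error"))
    }), schemes)
  }
  res <- purrr::imap_dfr(schemes, function(sch, sname) {
    purrr::map_dfr(seq_len(nrow(sch)), function(r) {
      train_ids <- sch$train[[r]]
      valid_ids <- sch$validation[[r]]
      grid <- tidyr::expand_grid(method = methods, model = models,
                                 trait = traits)
      purrr::pmap_dfr(grid, function(method, model, trait) {
        dplyr::mutate(
          fit_one_cell(method, model, trait, ct, spectra_mat, snp_mat,
                       train_ids, valid_ids, bayesb_chain, gbm_space),
          scheme = sname, replicate = r, .before = 1)
      })
    })
  })
  class(res) <- c("spectrakin_experiment", class(res))
  res
}

# G indexed by cow_id rather than animal id, for batch-out profiles.
cow_relabel_G <- function(bundle) {
  G <- bundle$G
  if (!is.null(G) && !is.null(bundle$cow_table)) {
    ids <- rownames(G)
    map <- match(ids, as.character(bundle$cow_table$animal))
    if (!anyNA(map)) {
      rownames(G) <- colnames(G) <- bundle$cow_table$cow_id[map]
    }
  }
  G
}

#' Summarize an experiment
#'
#' Mean and sample SD of R-squared, RMSE and slope across replicates for
#' every scheme x method x model x trait cell.
#'
#' @param results Output of [run_experiment()].
#' @return A summary tibble.
#' @export
summarize_experiment <- function(results) {
  results |>
    dplyr::group_by(.data$scheme, .data$method, .data$model, .data$trait) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      r2_mean = mean(.data$r2), r2_sd = sd(.data$r2),
      rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
      slope_mean = mean(.data$slope, na.rm = TRUE),
      slope_sd = sd(.data$slope, na.rm = TRUE),
      .groups = "drop")
}

#' Relative differences versus the FTIR-only baseline
#'
#' Computes, per scheme x method x trait, the relative difference of each
#' model's mean predictive ability against model M1.
#'
#' @param summary_tbl Output of [summarize_experiment()] including M1.
#' @return A tibble with `rd` (percent) per model.
#' @export
rd_table <- function(summary_tbl) {
  base <- summary_tbl |>
    dplyr::filter(.data$model == "M1") |>
    dplyr::select("scheme", "method", "trait", r2_m1 = "r2_mean")
  summary_tbl |>
    dplyr::filter(.data$model != "M1") |>
    dplyr::inner_join(base, by = c("scheme", "method", "trait")) |>
    dplyr::mutate(rd = relative_difference(.data$r2_mean, .data$r2_m1)) |>
    dplyr::select("scheme", "method", "model", "trait", "r2_mean",
                  "r2_m1", "rd")
}
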