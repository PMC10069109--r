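#' Hyperparameter search space for gradient boosting
#'
#' The random-search grids: number of trees 100 to 3000 in steps of 20,
#' learning rate 0 to 1 in steps of 0.1, maximum depth 5 to 80 in steps of
#' 5, minimum samples per leaf 20 to 100 in steps of 20, and at most
#' `max_models` sampled combinations.
#'
#' @param ntree,learn_rate,max_depth,min_leaf Grid vectors.
#' @param max_models Maximum sampled configurations.
#' @param rng_seed Integer seed for the random search.
#' @return A list of class `gbm_search_space`.
#' @export
gbm_search_space <- function(ntree = seq(100, 3000, by = 20),
                             learn_rate = seq(0, 1, by = 0.1),
                             max_depth = seq(5, 80, by = 5),
                             min_leaf = seq(20, 100, by = 20),
                             max_models = 100,
                             rng_seed = 1L) {
  structure(list(ntree = ntree, learn_rate = learn_rate,
                 max_depth = max_depth, min_leaf = min_leaf,
                 max_models = as.integer(max_models),
                 rng_seed = as.integer(rng_seed)),
            class = "gbm_search_space")
}

#' Sample hyperparameter configurations from the grid product
#'
#' Draws up to `max_models` unique configurations uniformly from the grid
#' product, seeded; when `max_models` covers the whole grid the enumeration
#' is exhaustive and duplicate-free.
#'
#' @param space A [gbm_search_space()].
#' @return A tibble with one row per configuration.
#' @export
sample_search_space <- function(space) {
  sizes <- c(length(space$ntree), length(space$learn_rate),
             length(space$max_depth), length(space$min_leaf))
  total <- prod(sizes)
  n_draw <- min(space$max_models, total)
  idx <- with_local_seed(space$rng_seed, {
    if (n_draw >= total) seq_len(total) else sample.int(total, n_draw)
  })
  idx0 <- idx - 1L
  tibble::tibble(
    ntree = space$ntree[idx0 %% sizes[1] + 1L],
    learn_rate = space$learn_rate[(idx0 %/% sizes[1]) %% sizes[2] + 1L],
    max_depth = space$max_depth[(idx0 %/% (sizes[1] * sizes[2])) %% sizes[3] + 1L],
    min_leaf = space$min_leaf[(idx0 %/% (sizes[1] * sizes[2] * sizes[3])) %% sizes[4] + 1L])
}

#' Fit a gradient-boosted tree ensemble with one configuration
#'
#' Stagewise squared-error boosting of depth-limited regression trees with
#' shrinkage `learn_rate`, honoring `min_leaf` observations per leaf. A
#' zero learning rate (a sampled grid point) or zero trees is guarded: the
#' ensemble predicts the training mean. Depth is capped at
#' `ceiling(log2(n))` when the grid value exceeds it; the cap is recorded.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response.
#' @param ntree,learn_rate,max_depth,min_leaf Hyperparameters.
#' @param nthread Threads for the backend (default 1, deterministic).
#' @return An object of class `gbm_fit`.
#' @export
gbm_fit <- function(X, y, ntree = 100, learn_rate = 0.1,
                    max_depth = 5, min_leaf = 20, nthread = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  if (sd(y) == 0) {
    stop_spectrakin("Degenerate response: y is constant.",
                    class = "spectrakin_data_error")
  }
  n <- nrow(X)
  depth_cap <- ceiling(log2(max(n, 2)))
  used_depth <- min(max_depth, depth_cap)
  if (learn_rate <= 0 || ntree <= 0) {
    return(structure(list(type = "mean", mean = mean(y),
                          feature_names = colnames(X),
                          params = list(ntree = ntree, learn_rate = learn_rate,
                                        max_depth = max_depth,
                                        min_leaf = min_leaf,
                                        used_depth = used_depth),
                          evaluation_log = NULL),
                     class = "gbm_fit"))
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = nthread)
  params <- list(objective = "reg:squarederror",
                 eta = learn_rate,
                 max_depth = used_depth,
                 min_child_weight = min_leaf,
                 lambda = 0, alpha = 0,
                 subsample = 1, colsample_bytree = 1,
                 tree_method = "hist", max_bin = 64,
                 nthread = nthread,
                 base_score = mean(y))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = ntree,
                                evals = list(train = dtrain),
                                verbose = 0)
  structure(list(type = "boosted", booster = booster,
                 feature_names = colnames(X),
                 mean = mean(y),
                 params = list(ntree = ntree, learn_rate = learn_rate,
                               max_depth = max_depth, min_leaf = min_leaf,
                               used_depth = used_depth),
                 evaluation_log = attributes(booster)$evaluation_log),
            class = "gbm_fit")
}

#' @export
predict.gbm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$type == "mean") return(rep(object$mean, nrow(newdata)))
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' Relative variable importance from split improvements
#'
#' Collects the error-reduction (gain) of every internal split, squares
#' and sums the improvements per feature, and normalizes to percentages
#' summing to 100.
#'
#' @param model A [gbm_fit()] ensemble with at least one split.
#' @return A tibble `feature`, `vi` (percent), sorted by the original
#'   feature order, zero for features never used.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "gbm_fit"))
  if (model$type == "mean") {
    stop_spectrakin("Ensemble has no splits: variable importance undefined.",
                    class = "spectrakin_undefined_error")
  }
  tr <- xgboost::xgb.model.dt.tree(model = model$booster)
  tr <- tr[tr$Feature != "Leaf", , drop = FALSE]
  if (nrow(tr) == 0) {
    stop_spectrakin("Ensemble has no splits: variable importance undefined.",
                    class = "spectrakin_undefined_error")
  }
  raw <- tapply(tr$Gain^2, tr$Feature, sum)
  vi <- setNames(numeric(length(model$feature_names)), model$feature_names)
  vi[names(raw)] <- raw
  vi <- 100 * vi / sum(vi)
  tibble::tibble(feature = names(vi), vi = unname(vi))
}

#' Random search with inner five-fold tuning
#'
#' For each sampled configuration, runs five-fold cross-validation inside
#' the training set, scores the pooled out-of-fold predictions by R-squared
#' (squared Pearson correlation) and MSE, selects the configuration with
#' the highest R-squared (ties broken by lowest MSE), and refits it on the
#' full training set.
#'
#' @param X Training feature matrix.
#' @param y Training response.
#' @param space A [gbm_search_space()].
#' @param inner_folds Number of inner folds (default 5).
#' @return A `gbm_fit` for the winning configuration, with the tuning log
#'   attached as attribute `tuning` and the chosen row as `chosen`.
#' @export
gbm_tune <- function(X, y, space = gbm_search_space(), inner_folds = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) {
    stop_spectrakin("Need at least 10 training rows for inner tuning.",
                    class = "spectrakin_data_error")
  }
  if (sd(y) == 0) {
    stop_spectrakin("Degenerate response: y is constant.",
                    class = "spectrakin_data_error")
  }
  configs <- sample_search_space(space)
  folds <- with_local_seed(space$rng_seed + 1L, {
    sample(rep_len(seq_len(inner_folds), n))
  })
  score <- purrr::pmap_dfr(configs, function(ntree, learn_rate, max_depth,
                                             min_leaf) {
    pred <- numeric(n)
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      fit <- gbm_fit(X[tr, , drop = FALSE], y[tr], ntree = ntree,
                     learn_rate = learn_rate, max_depth = max_depth,
                     min_leaf = min_leaf)
      pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
    }
    r2 <- if (sd(pred) == 0) 0 else cor(y, pred)^2
    tibble::tibble(ntree = ntree, learn_rate = learn_rate,
                   max_depth = max_depth, min_leaf = min_leaf,
                   inner_r2 = r2, inner_mse = mean((y - pred)^2))
  })
  ord <- order(-score$inner_r2, score$inner_mse)
  best <- score[ord[1], ]
  fit <- gbm_fit(X, y, ntree = best$ntree, learn_rate = best$learn_rate,
                 max_depth = best$max_depth, min_leaf = best$min_leaf)
  attr(fit, "tuning") <- score
  attr(fit, "chosen") <- best
  fit
}

#' Wavelengths with variable importance above a threshold
#'
#' @param vi A tibble from [variable_importance()] (or a named numeric
#'   vector of percentages).
#' @param threshold Percent threshold; strictly greater retained (default
#'   0.8).
#' @return Character vector of selected feature names.
#' @export
significant_wavelengths <- function(vi, threshold = 0.8) {
  if (is.data.frame(vi)) {
    vi <- setNames(vi$vi, vi$feature)
  }
  names(vi)[vi > threshold]
}

#' Overlap counts between selected-feature sets
#'
#' Pairwise intersection sizes between named feature sets, e.g. the
#' significant wavelengths per trait or per method.
#'
#' @param sets Named list of character vectors.
#' @return A tibble `set1`, `set2`, `n1`, `n2`, `overlap`, `jaccard`.
#' @export
vi_overlap <- function(sets) {
  nm <- names(sets)
  combos <- utils::combn(seq_along(sets), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    ov <- length(intersect(sets[[a]], sets[[b]]))
    un <- length(union(sets[[a]], sets[[b]]))
    tibble::tibble(set1 = nm[a], set2 = nm[b],
                   n1 = length(sets[[a]]), n2 = length(sets[[b]]),
                   overlap = ov,
                   jaccard = if (un > 0) ov / un else NA_real_)
  })
}

#' @rdname tidy.spectrakin
#' @export
tidy.gbm_fit <- function(x, ...) variable_importance(x)

#' @rdname tidy.spectrakin
#' @export
glance.gbm_fit <- function(x, ...) {
  chosen <- attr(x, "chosen")
  tibble::tibble(
    type = x$type,
    ntree = x$params$ntree, learn_rate = x$params$learn_rate,
    max_depth = x$params$max_depth, min_leaf = x$params$min_leaf,
    used_depth = x$params$used_depth,
    inner_r2 = if (is.null(chosen)) NA_real_ else chosen$inner_r2,
    inner_mse = if (is.null(chosen)) NA_real_ else chosen$inner_mse)
}
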