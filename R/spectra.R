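#' FTIR spectra container
#'
#' A light container for per-cow FTIR spectra: a numeric matrix with one row
#' per replicate spectrum and one column per wavenumber, plus the descending
#' wavenumber axis (cm-1), per-row cow ids and replicate tags, the
#' measurement unit and a standardization flag.
#'
#' @param values Numeric matrix, rows = replicate spectra, columns =
#'   wavenengths.
#' @param wavenumbers Strictly monotone numeric axis, length = `ncol(values)`.
#' @param cow_id Character vector, one id per row.
#' @param replicate Integer replicate tag per row.
#' @param unit `"transmittance"` or `"absorbance"`.
#' @param standardized Logical; whether columns are mean-0, SD-1.
#' @return An object of class `spectra_matrix`.
#' @export
as_spectra <- function(values, wavenumbers,
                       cow_id = rownames(values),
                       replicate = rep(1L, nrow(values)),
                       unit = c("absorbance", "transmittance"),
                       standardized = FALSE) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (length(wavenumbers) != ncol(values)) {
    stop_spectrakin("Wavenumber axis length must match the number of columns.",
                    class = "spectrakin_spectra_error")
  }
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop_spectrakin("Wavenumber axis must be strictly monotone.",
                    class = "spectrakin_spectra_error")
  }
  if (is.null(cow_id)) cow_id <- sprintf("row%04d", seq_len(nrow(values)))
  structure(list(values = unname(values),
                 wavenumbers = as.numeric(wavenumbers),
                 cow_id = as.character(cow_id),
                 replicate = as.integer(replicate),
                 unit = unit,
                 standardized = isTRUE(standardized)),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectra_matrix> %d spectra (%d cows) x %d wavenumbers [%.0f..%.0f cm-1], %s%s\n",
    nrow(x$values), length(unique(x$cow_id)), ncol(x$values),
    x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)],
    x$unit, if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

#' Convert transmittance spectra to absorbance
#'
#' Applies the spectroscopy transform A = log10(1/T) elementwise. All
#' transmittance values must lie in (0, 1].
#'
#' @param spectra A [spectra_matrix] in transmittance units.
#' @return The same object in absorbance units; axis unchanged.
#' @export
transmittance_to_absorbance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (spectra$unit != "transmittance") {
    stop_spectrakin("Spectra are already in absorbance units.",
                    class = "spectrakin_spectra_error")
  }
  bad <- which(spectra$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_spectrakin(
      sprintf("Non-positive transmittance at row %d, wavenumber %.1f cm-1.",
              bad[1, 1], spectra$wavenumbers[bad[1, 2]]),
      class = "spectrakin_domain_error")
  }
  spectra$values <- log10(1 / spectra$values)
  spectra$unit <- "absorbance"
  spectra
}

#' Standardize spectral channels
#'
#' Centers and scales every wavelength column to mean 0 and sample SD 1
#' (n - 1 denominator). Constant channels are an error, reported by
#' wavenumber.
#'
#' @param spectra A [spectra_matrix] in absorbance units.
#' @return The standardized object (`standardized = TRUE`).
#' @export
standardize_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  sds <- apply(spectra$values, 2, sd)
  if (any(sds == 0)) {
    stop_spectrakin(
      "Zero-variance channels at wavenumbers: ",
      paste(round(spectra$wavenumbers[sds == 0], 1), collapse = ", "),
      class = "spectrakin_degenerate_channel_error")
  }
  spectra$values <- scale(spectra$values)[, , drop = FALSE]
  attr(spectra$values, "scaled:center") <- NULL
  attr(spectra$values, "scaled:scale") <- NULL
  spectra$standardized <- TRUE
  spectra
}

#' Average replicate spectra per cow
#'
#' Collapses the replicate rows of each cow into their arithmetic
#' per-channel mean (the study design records two spectra per milk sample,
#' standardized first and then averaged).
#'
#' @param spectra A [spectra_matrix]; every cow must have at least one row.
#' @return A [spectra_matrix] with one row per cow, ordered by first
#'   appearance.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  ids <- unique(spectra$cow_id)
  idx <- split(seq_along(spectra$cow_id), factor(spectra$cow_id, levels = ids))
  vals <- do.call(rbind, lapply(idx, function(i) {
    colMeans(spectra$values[i, , drop = FALSE])
  }))
  as_spectra(vals, spectra$wavenumbers, cow_id = ids,
             replicate = rep(1L, length(ids)), unit = spectra$unit,
             standardized = spectra$standardized)
}

#' Mahalanobis outlier screening in principal-component space
#'
#' Projects the (standardized, replicate-averaged) spectra onto the
#' principal components explaining at least `var_explained` of the total
#' variance (capped at `min(n - 1, p)`), computes each cow's squared
#' Mahalanobis distance in that score space, and removes cows whose squared
#' distance exceeds the chi-square(k) quantile at significance `alpha`.
#'
#' @param spectra A replicate-averaged [spectra_matrix].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param var_explained PCA variance fraction retained; default 0.95.
#' @return A list: `spectra` (filtered), `removed_ids`, `distances` (tibble
#'   with `cow_id`, `d2`, `removed`), `k` (components used), and
#'   `threshold`.
#' @export
spectra_outlier_qc <- function(spectra, alpha = 0.05, var_explained = 0.95) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (alpha <= 0 || alpha >= 1) {
    stop_spectrakin("`alpha` must lie in (0, 1).",
                    class = "spectrakin_parameter_error")
  }
  if (anyDuplicated(spectra$cow_id)) {
    stop_spectrakin("Average replicates before outlier screening.",
                    class = "spectrakin_spectra_error")
  }
  n <- nrow(spectra$values)
  pc <- prcomp(spectra$values, center = TRUE, scale. = FALSE)
  ve <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- min(which(ve >= var_explained))
  k <- min(k, n - 1, ncol(spectra$values))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d2 <- rowSums(sweep(scores, 2, pc$sdev[seq_len(k)], "/")^2)
  threshold <- qchisq(1 - alpha, df = k)
  removed <- d2 > threshold
  out <- spectra
  out$values <- spectra$values[!removed, , drop = FALSE]
  out$cow_id <- spectra$cow_id[!removed]
  out$replicate <- spectra$replicate[!removed]
  list(spectra = out,
       removed_ids = spectra$cow_id[removed],
       distances = tibble::tibble(cow_id = spectra$cow_id, d2 = d2,
                                  removed = removed),
       k = k, threshold = threshold)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in order: transmittance-to-absorbance (if needed), channel
#' standardization, replicate averaging, and Mahalanobis outlier screening.
#' Water absorption regions are retained throughout; columns are never
#' dropped.
#'
#' @inheritParams spectra_outlier_qc
#' @param spectra A [spectra_matrix] (replicates allowed).
#' @return As [spectra_outlier_qc()], on the processed spectra.
#' @export
preprocess_spectra <- function(spectra, alpha = 0.05, var_explained = 0.95) {
  if (spectra$unit == "transmittance") {
    spectra <- transmittance_to_absorbance(spectra)
  }
  spectra <- standardize_spectra(spectra)
  spectra <- average_replicates(spectra)
  spectra_outlier_qc(spectra, alpha = alpha, var_explained = var_explained)
}

#' Spectra matrix for modelling
#'
#' Extracts the plain numeric matrix (rows = cows, rownames = cow ids) from
#' a [spectra_matrix], for use as a predictor block.
#'
#' @param spectra A [spectra_matrix] with one row per cow.
#' @return A numeric matrix with cow-id rownames and wavenumber colnames.
#' @export
spectra_values <- function(spectra) {
  v <- spectra$values
  rownames(v) <- spectra$cow_id
  colnames(v) <- sprintf("wn%.1f", spectra$wavenumbers)
  v
}
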