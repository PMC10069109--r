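#' Days-in-milk and parity classes
#'
#' DIM is binned into six classes (under 60; 60-120; 121-180; 181-240;
#' 241-300; over 300 days) and parity into four (1, 2, 3, 4-and-over).
#'
#' @param dim Days in milk (non-negative).
#' @param parity Parity (lactation number, >= 1).
#' @return Integer class codes.
#' @export
dim_class <- function(dim) {
  if (any(is.na(dim) | dim < 0)) {
    stop_spectrakin("DIM must be non-negative and non-missing.",
                    class = "spectrakin_validation_error")
  }
  cl <- findInterval(dim, c(60, 121, 181, 241, 301)) + 1L
  as.integer(cl)
}

#' @rdname dim_class
#' @export
parity_class <- function(parity) {
  if (any(is.na(parity) | parity < 1)) {
    stop_spectrakin("Parity must be >= 1 and non-missing.",
                    class = "spectrakin_validation_error")
  }
  as.integer(pmin(parity, 4L))
}

#' Integrate cow table, spectra and genotypes into one analysis bundle
#'
#' Runs the spectral preprocessing pipeline (absorbance transform,
#' standardization, replicate averaging, Mahalanobis QC), the genotype QC,
#' and inner-joins the three sources on cow identity, keeping cows with a
#' phenotype record, a surviving spectrum and QC-passed genotypes. DIM and
#' parity are mapped to their classes if the class columns are absent.
#' Builds the kinship bundle over the pedigree with the aligned cows as
#' genotyped block. Per-source attrition is recorded in the `manifest`.
#'
#' @param cow_table Tibble with `cow_id`, `animal`, `herd`, `batch`,
#'   `dim` (or `dim_class`), `parity` (or `parity_class`) and trait
#'   columns.
#' @param spectra A [spectra_matrix] (replicates allowed).
#' @param genotypes A `genotype_set` or dosage matrix with animal-id
#'   rownames.
#' @param pedigree Pedigree tibble covering the cows and their ancestors.
#' @param alpha Spectral QC significance level.
#' @param maf_min,hwe_p,call_rate Genotype QC thresholds.
#' @param blend_weight Genomic blending weight for the kinship bundle.
#' @return A list of class `cow_bundle`: `cow_table`, `spectra`,
#'   `spectra_mat`, `genotypes`, `snp_mat`, `kinship`, `G`, `manifest`.
#' @export
load_and_align <- function(cow_table, spectra, genotypes, pedigree,
                           alpha = 0.05, maf_min = 0.05, hwe_p = 1e-5,
                           call_rate = 0.95, blend_weight = 0.95) {
  cow_table <- tibble::as_tibble(cow_table)
  if (anyDuplicated(cow_table$cow_id)) {
    stop_spectrakin("Duplicate cow ids in the cow table.",
                    class = "spectrakin_validation_error")
  }
  if (!"dim_class" %in% names(cow_table)) {
    cow_table$dim_class <- dim_class(cow_table$dim)
  }
  if (!"parity_class" %in% names(cow_table)) {
    cow_table$parity_class <- parity_class(cow_table$parity)
  }
  n0 <- nrow(cow_table)

  qc <- preprocess_spectra(spectra, alpha = alpha)
  sp <- qc$spectra
  n_spectra <- length(sp$cow_id)

  geno <- genotype_qc(genotypes, maf_min = maf_min, hwe_p = hwe_p,
                      call_rate = call_rate)

  keep <- cow_table$cow_id %in% sp$cow_id &
    as.character(cow_table$animal) %in% geno$sample_ids &
    stats::complete.cases(cow_table)
  dropped <- cow_table$cow_id[!keep]
  cow_table <- cow_table[keep, , drop = FALSE]
  if (nrow(cow_table) == 0) {
    stop_spectrakin("No cows remain after data integration.",
                    class = "spectrakin_validation_error")
  }

  keep_rows <- match(cow_table$cow_id, sp$cow_id)
  sp$values <- sp$values[keep_rows, , drop = FALSE]
  sp$cow_id <- sp$cow_id[keep_rows]
  sp$replicate <- sp$replicate[keep_rows]
  spectra_mat <- spectra_values(sp)

  geno$study_ids <- as.character(cow_table$animal)
  kin <- kinship_bundle(pedigree, geno, blend_weight = blend_weight)
  snp_mat <- geno$dosages[as.character(cow_table$animal), , drop = FALSE]

  manifest <- list(
    n_input = n0,
    n_after_spectra_qc = n_spectra,
    spectra_removed = qc$removed_ids,
    genotype_attrition = attr(geno, "attrition"),
    n_aligned = nrow(cow_table),
    dropped_ids = dropped)

  structure(list(cow_table = cow_table, spectra = sp,
                 spectra_mat = spectra_mat, genotypes = geno,
                 snp_mat = snp_mat, kinship = kin, G = kin$G,
                 manifest = manifest),
            class = "cow_bundle")
}

#' @export
print.cow_bundle <- function(x, ...) {
  cat(sprintf(
    "<cow_bundle> %d cows aligned (from %d), %d wavelengths, %d SNPs\n",
    nrow(x$cow_table), x$manifest$n_input, ncol(x$spectra_mat),
    ncol(x$snp_mat)))
  invisible(x)
}

#' Spectra CSV I/O
#'
#' The spectra dialect is a delimited matrix: columns `cow_id`,
#' `replicate`, then one column per wavenumber (header = the wavenumber in
#' cm-1).
#'
#' @param spectra A [spectra_matrix].
#' @param path File path.
#' @param unit Measurement unit when reading.
#' @return `read_spectra_csv()` returns a [spectra_matrix];
#'   `write_spectra_csv()` its path, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(cow_id = spectra$cow_id, replicate = spectra$replicate,
                   spectra$values, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("%.6f", spectra$wavenumbers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, unit = c("absorbance", "transmittance")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, check.names = FALSE)
  wn <- as.numeric(names(df)[-(1:2)])
  as_spectra(as.matrix(df[, -(1:2), drop = FALSE]), wn,
             cow_id = as.character(df$cow_id),
             replicate = as.integer(df$replicate), unit = unit)
}

#' Dosage-matrix CSV I/O
#'
#' A documented 0/1/2 dosage dialect: first column `sample_id`, then one
#' integer column per SNP; empty cells are missing calls.
#'
#' @param genotypes A `genotype_set` or dosage matrix.
#' @param path File path.
#' @return `read_dosage_csv()` returns a `genotype_set`.
#' @export
write_dosage_csv <- function(genotypes, path) {
  dos <- if (inherits(genotypes, "genotype_set")) genotypes$dosages else genotypes
  df <- data.frame(sample_id = rownames(dos), dos, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dosage_csv
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- as.character(df$sample_id)
  structure(list(
    dosages = dos,
    snp_meta = tibble::tibble(snp_id = colnames(dos), chrom = 1L,
                              pos = seq_len(ncol(dos)), autosomal = TRUE),
    sample_ids = rownames(dos),
    study_ids = rownames(dos)), class = "genotype_set")
}

#' Pedigree CSV I/O
#'
#' Triplet dialect `animal,sire,dam`, with 0 marking an unknown parent.
#'
#' @param pedigree Pedigree tibble.
#' @param path File path.
#' @return `read_pedigree_csv()` returns a tibble.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  utils::write.csv(pedigree[, c("animal", "sire", "dam")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' PLINK-style text genotype I/O
#'
#' Writes/reads the `.ped`/`.map` text dialect: the `.map` file holds
#' chromosome, SNP id, genetic distance (0) and position; the `.ped` file
#' holds family/individual ids, parents, sex, phenotype, and two
#' allele columns per SNP coded `1`/`2` (`0 0` = missing). Dosage counts
#' the `2` allele.
#'
#' @param genotypes A `genotype_set`.
#' @param prefix Path prefix (files `<prefix>.ped` and `<prefix>.map`).
#' @return `read_plink()` returns a `genotype_set`.
#' @export
write_plink <- function(genotypes, prefix) {
  dos <- genotypes$dosages
  meta <- genotypes$snp_meta
  utils::write.table(
    data.frame(meta$chrom, meta$snp_id, 0, meta$pos),
    paste0(prefix, ".map"), row.names = FALSE, col.names = FALSE,
    quote = FALSE, sep = "\t")
  n <- nrow(dos); m <- ncol(dos)
  al <- matrix("0", n, 2 * m)
  a1 <- ifelse(is.na(dos), "0", ifelse(dos >= 1, "2", "1"))
  a2 <- ifelse(is.na(dos), "0", ifelse(dos == 2, "2", "1"))
  al[, seq(1, 2 * m, by = 2)] <- a1
  al[, seq(2, 2 * m, by = 2)] <- a2
  ped <- cbind("FAM1", rownames(dos), "0", "0", "0", "-9", al)
  utils::write.table(ped, paste0(prefix, ".ped"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = " ")
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- ncol(al) / 2
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  dos <- (a1 == "2") + (a2 == "2")
  dos[a1 == "0" | a2 == "0"] <- NA
  dos <- matrix(as.numeric(dos), nrow(ped), m,
                dimnames = list(ids, map$snp_id))
  structure(list(
    dosages = dos,
    snp_meta = tibble::tibble(snp_id = map$snp_id, chrom = map$chrom,
                              pos = map$pos, autosomal = TRUE),
    sample_ids = ids, study_ids = ids), class = "genotype_set")
}

#' Run the full pipeline end-to-end
#'
#' Simulates (or accepts) a dataset, integrates and QCs the three sources,
#' estimates variance components per trait with the single-step animal
#' model, runs the prediction factorial, and returns every artifact plus a
#' run manifest. Sizes below the study scale keep this a desk-scale smoke
#' run; every component accepts larger configurations.
#'
#' @param config A [sim_config()] describing the population (or a
#'   pre-built dataset list from [simulate_dataset()]).
#' @param traits Traits to analyse (default: all in the dataset).
#' @param methods,models,schemes Passed to [run_experiment()].
#' @param gibbs_chain A [chain_config()] for the variance-component
#'   sampler.
#' @param bayesb_chain,gbm_space Passed to [run_experiment()].
#' @param seed Master seed for fold assignment.
#' @return A list: `bundle`, `variance_components` (glance tibble per
#'   trait), `results`, `summary`, `rd`, `manifest`.
#' @export
run_all <- function(config = sim_config(),
                    traits = NULL,
                    methods = c("BayesB", "GBM"),
                    models = c("M1", "M4"),
                    schemes = c("tenfold", "batch_out", "herd_out"),
                    gibbs_chain = chain_config(20000, 5000, 5),
                    bayesb_chain = chain_config(3000, 1000, 2),
                    gbm_space = gbm_search_space(max_models = 5),
                    seed = 1L) {
  ds <- if (inherits(config, "sim_config")) simulate_dataset(config) else config
  traits <- traits %||% ds$config$traits$trait
  bundle <- load_and_align(ds$cow_table, ds$spectra, ds$genotypes,
                           ds$pedigree)
  vc <- purrr::map_dfr(traits, function(tr) {
    glance(animal_model_gibbs(bundle$cow_table, tr, bundle$kinship,
                              chain = gibbs_chain))
  })
  results <- run_experiment(bundle, traits = traits, methods = methods,
                            models = models, schemes = schemes, seed = seed,
                            bayesb_chain = bayesb_chain,
                            gbm_space = gbm_space)
  summary_tbl <- summarize_experiment(results)
  rd <- if ("M1" %in% models && length(models) > 1) {
    rd_table(summary_tbl)
  } else NULL
  manifest <- c(bundle$manifest,
                list(seed = seed, traits = traits, methods = methods,
                     models = models,
                     schemes = if (is.character(schemes)) schemes else
                       names(schemes)))
  list(bundle = bundle, variance_components = vc, results = results,
       summary = summary_tbl, rd = rd, manifest = manifest)
}
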