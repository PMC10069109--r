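#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Exact test (mid-less, two-sided by probability ordering of heterozygote
#' counts) when the genotyped count is below 1000, chi-square test with one
#' degree of freedom otherwise.
#'
#' @param n0,n1,n2 Counts of dosage-0 homozygotes, heterozygotes and
#'   dosage-2 homozygotes.
#' @return A p-value.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  if (n < 1000) {
    # exact test: enumerate heterozygote counts compatible with the
    # observed allele counts, sum probabilities <= that of the observed
    rare <- min(2 * n0 + n1, 2 * n2 + n1)
    het_obs <- n1
    hets <- seq(rare %% 2, rare, by = 2)
    logp <- vapply(hets, function(h) {
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
        h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
        lgamma(2 * n + 1)
    }, numeric(1))
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[match(het_obs, hets)] * (1 + 1e-12)]))
  } else {
    p <- (2 * n2 + n1) / (2 * n)
    e <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    pchisq(x2, df = 1, lower.tail = FALSE)
  }
}

#' SNP and sample quality control
#'
#' Applies, in a fixed order, the marker and sample filters of the study:
#' (1) drop non-autosomal SNPs; (2) drop SNPs with call rate below
#' `call_rate`; (3) drop SNPs with minor allele frequency strictly below
#' `maf_min`; (4) drop SNPs with Hardy-Weinberg p-value at or below
#' `hwe_p`; (5) drop samples with call rate below `call_rate`. Remaining
#' missing dosages are imputed to twice the observed second-allele
#' frequency (mean imputation).
#'
#' @param genotypes A `genotype_set` (see [simulate_genotypes()]) or a
#'   dosage matrix with sample rownames; `NA` marks missing calls.
#' @param maf_min Minimum minor allele frequency (strictly lower removed).
#' @param hwe_p HWE p-value threshold (p <= `hwe_p` removed).
#' @param call_rate Minimum SNP and sample call rate (strictly lower
#'   removed).
#' @return A `genotype_set` with imputed numeric dosages and an
#'   `attrition` attribute: a tibble of per-step counts.
#' @export
genotype_qc <- function(genotypes, maf_min = 0.05, hwe_p = 1e-5,
                        call_rate = 0.95) {
  if (inherits(genotypes, "genotype_set")) {
    dos <- genotypes$dosages
    meta <- genotypes$snp_meta
  } else {
    dos <- as.matrix(genotypes)
    meta <- tibble::tibble(
      snp_id = colnames(dos) %||% sprintf("snp%05d", seq_len(ncol(dos))),
      chrom = 1L, pos = seq_len(ncol(dos)), autosomal = TRUE)
  }
  if (is.null(rownames(dos))) {
    rownames(dos) <- sprintf("s%05d", seq_len(nrow(dos)))
  }
  steps <- list()
  note <- function(step, snps, samples) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = step, n_snps = snps, n_samples = samples)
  }
  note("input", ncol(dos), nrow(dos))

  keep <- meta$autosomal %||% rep(TRUE, ncol(dos))
  dos <- dos[, keep, drop = FALSE]; meta <- meta[keep, ]
  note("autosomal", ncol(dos), nrow(dos))

  cr_snp <- colMeans(!is.na(dos))
  keep <- cr_snp >= call_rate
  dos <- dos[, keep, drop = FALSE]; meta <- meta[keep, ]
  note("snp_call_rate", ncol(dos), nrow(dos))

  p2 <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p2, 1 - p2)
  keep <- maf >= maf_min
  dos <- dos[, keep, drop = FALSE]; meta <- meta[keep, ]
  note("maf", ncol(dos), nrow(dos))

  hwe <- apply(dos, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- hwe > hwe_p
  dos <- dos[, keep, drop = FALSE]; meta <- meta[keep, ]
  note("hwe", ncol(dos), nrow(dos))

  cr_sample <- rowMeans(!is.na(dos))
  keep_s <- cr_sample >= call_rate
  dos <- dos[keep_s, , drop = FALSE]
  note("sample_call_rate", ncol(dos), nrow(dos))

  if (ncol(dos) == 0 || nrow(dos) == 0) {
    stop_spectrakin(
      "Quality control removed all data. Attrition: ",
      paste(sprintf("%s=%d SNPs/%d samples",
                    dplyr::bind_rows(steps)$step,
                    dplyr::bind_rows(steps)$n_snps,
                    dplyr::bind_rows(steps)$n_samples), collapse = "; "),
      class = "spectrakin_qc_error")
  }

  rn <- rownames(dos)
  cn <- colnames(dos)
  dos <- apply(dos, 2, function(g) {
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  dimnames(dos) <- list(rn, cn)

  out <- structure(list(
    dosages = dos,
    snp_meta = meta,
    sample_ids = rownames(dos),
    study_ids = intersect(
      if (inherits(genotypes, "genotype_set"))
        genotypes$study_ids else rownames(dos),
      rownames(dos))
  ), class = "genotype_set")
  attr(out, "attrition") <- dplyr::bind_rows(steps)
  out
}

# Topologically validate and order a pedigree tibble (animal, sire, dam).
order_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree[, c("animal", "sire", "dam")])
  n <- nrow(ped)
  pos <- match(ped$animal, ped$animal)
  sp <- match(ped$sire, ped$animal)  # NA for unknown/founder
  dp <- match(ped$dam, ped$animal)
  ok <- (is.na(sp) | sp < seq_len(n)) & (is.na(dp) | dp < seq_len(n))
  if (all(ok)) return(pedigree)
  # attempt a topological sort; failure indicates a cycle
  placed <- logical(n)
  order_idx <- integer(0)
  repeat {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      (is.na(sp[i]) || placed[sp[i]]) && (is.na(dp[i]) || placed[dp[i]])
    }, logical(1)))
    if (length(ready) == 0) break
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
  }
  if (!all(placed)) {
    stop_spectrakin("Pedigree contains a cycle (an animal is its own ancestor).",
                    class = "spectrakin_pedigree_error")
  }
  pedigree[order_idx, , drop = FALSE]
}

#' Numerator relationship matrix from a pedigree
#'
#' Computes the tabular (recursive) pedigree relationship matrix A. Parents
#' must precede offspring; if they do not, the pedigree is topologically
#' sorted first, and a cycle raises an error.
#'
#' @param pedigree A data frame with columns `animal`, `sire`, `dam`
#'   (0 or `NA` = unknown parent).
#' @return A symmetric matrix with animal ids as dimnames, in the
#'   (possibly re-sorted) pedigree order.
#' @export
build_A <- function(pedigree) {
  ped <- order_pedigree(pedigree)
  sire <- match(ped$sire, ped$animal)
  dam <- match(ped$dam, ped$animal)
  sire[is.na(sire)] <- 0L
  dam[is.na(dam)] <- 0L
  A <- .amat_tabular(as.integer(sire) - 1L, as.integer(dam) - 1L)
  dimnames(A) <- list(as.character(ped$animal), as.character(ped$animal))
  A
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers the dosage matrix columns by twice the observed second-allele
#' frequency and scales by `2 * sum(p_j * (1 - p_j))`:
#' `G = Z Z' / (2 sum p_j (1 - p_j))` with `Z = M - 2p`.
#'
#' @param M Numeric dosage matrix (samples x SNPs, no missing values).
#' @param p Optional second-allele frequencies; observed frequencies by
#'   default.
#' @return A symmetric genomic relationship matrix with sample dimnames.
#' @export
build_G <- function(M, p = NULL) {
  M <- as.matrix(M)
  if (anyNA(M)) {
    stop_spectrakin("Dosage matrix contains missing values; run genotype_qc().",
                    class = "spectrakin_kinship_error")
  }
  if (is.null(p)) p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop_spectrakin("All SNPs are monomorphic: zero scaling denominator.",
                    class = "spectrakin_kinship_error")
  }
  Z <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' Replaces G by `w * G + (1 - w) * A22` to guarantee invertibility before
#' the single-step combination.
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationship sub-matrix of the genotyped animals, in
#'   the same order.
#' @param weight Genomic weight `w`; default 0.95.
#' @return The blended matrix.
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  stopifnot(all(dim(G) == dim(A22)))
  weight * G + (1 - weight) * A22
}

#' Inverse of the single-step combined relationship matrix
#'
#' Builds `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, with the correction
#' placed at the genotyped animals' positions in A's ordering. `G` should
#' already be blended (see [blend_G()]) so it is invertible.
#'
#' @param A Full pedigree relationship matrix with animal-id dimnames.
#' @param A22 Genotyped-subset block of `A` (dimnames identify the
#'   genotyped animals).
#' @param G (Blended) genomic relationship matrix in the same order as
#'   `A22`.
#' @return The symmetric `H^-1` matrix in A's ordering.
#' @export
build_Hinv <- function(A, A22, G) {
  ids <- rownames(A)
  if (nrow(A22) == 0) {
    # no genotyped animals: no correction block
    Hinv <- chol2inv(chol(A))
    dimnames(Hinv) <- dimnames(A)
    return((Hinv + t(Hinv)) / 2)
  }
  gids <- rownames(A22) %||% rownames(G)
  if (is.null(ids) || is.null(gids)) {
    stop_spectrakin("A and A22/G need id dimnames to align the correction block.",
                    class = "spectrakin_kinship_error")
  }
  idx <- match(gids, ids)
  if (anyNA(idx)) {
    stop_spectrakin("Genotyped ids missing from A.",
                    class = "spectrakin_kinship_error")
  }
  Ainv <- chol2inv(chol(A))
  Hinv <- Ainv
  if (length(idx) > 0) {
    Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) {
      stop_spectrakin(
        sprintf("G is not invertible after blending (rcond = %.3g).",
                rcond(G)),
        class = "spectrakin_numerical_error")
    })
    A22inv <- chol2inv(chol(A22))
    Hinv[idx, idx] <- Hinv[idx, idx] + (Ginv - A22inv)
  }
  dimnames(Hinv) <- dimnames(A)
  (Hinv + t(Hinv)) / 2
}

#' Build the full kinship bundle for a dataset
#'
#' Computes A over the pedigree, the genotyped block A22, the (blended)
#' genomic matrix G over the QC-passed genotyped study animals, and the
#' single-step `H^-1`, all sharing one animal ordering.
#'
#' @param pedigree Pedigree tibble (`animal`, `sire`, `dam`).
#' @param genotypes A QC-passed `genotype_set`; its `study_ids` define the
#'   genotyped block.
#' @param blend_weight Genomic weight for [blend_G()].
#' @return A list of class `kinship_bundle`: `A`, `A22`, `G` (blended),
#'   `G_raw`, `Hinv`, `id_order`, `genotyped_ids`.
#' @export
kinship_bundle <- function(pedigree, genotypes, blend_weight = 0.95) {
  A <- build_A(pedigree)
  gids <- intersect(genotypes$study_ids, rownames(A))
  M <- genotypes$dosages[gids, , drop = FALSE]
  G_raw <- build_G(M)
  A22 <- A[gids, gids, drop = FALSE]
  G <- blend_G(G_raw, A22, weight = blend_weight)
  Hinv <- build_Hinv(A, A22, G)
  structure(list(A = A, A22 = A22, G = G, G_raw = G_raw, Hinv = Hinv,
                 id_order = rownames(A), genotyped_ids = gids),
            class = "kinship_bundle")
}
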