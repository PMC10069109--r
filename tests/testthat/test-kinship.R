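test_that("marker QC enforces the documented thresholds and order", {
  set.seed(1)
  n <- 500
  # columns engineered around the boundaries
  maf_049 <- c(rep(0, n - 49), rep(1, 49))           # freq 49/1000 = 0.049
  maf_050 <- c(rep(0, n - 50), rep(1, 50))           # exactly 0.050
  hwe_bad <- rep(1, n)                               # all heterozygous
  normal <- rbinom(n, 2, 0.3)
  low_cr <- c(rep(NA, 30), rbinom(n - 30, 2, 0.3))   # call rate 0.94
  dos <- cbind(maf_049 = maf_049, maf_050 = maf_050, hwe_bad = hwe_bad,
               normal = normal, low_cr = low_cr, sexchr = rbinom(n, 2, 0.4))
  rownames(dos) <- sprintf("id%03d", seq_len(n))
  # one sample with 3/6 missing -> call rate 0.5
  dos[1, c("maf_049", "normal", "hwe_bad")] <- NA
  gs <- structure(list(
    dosages = dos,
    snp_meta = tibble::tibble(snp_id = colnames(dos), chrom = c(1, 1, 2, 2, 3, 30),
                              pos = 1:6, autosomal = c(rep(TRUE, 5), FALSE)),
    sample_ids = rownames(dos), study_ids = rownames(dos)),
    class = "genotype_set")
  qc <- genotype_qc(gs)
  kept <- qc$snp_meta$snp_id
  expect_false("sexchr" %in% kept)     # non-autosomal dropped first
  expect_false("low_cr" %in% kept)     # SNP call rate 0.94 < 0.95
  expect_false("maf_049" %in% kept)    # strictly below 0.05
  expect_true("maf_050" %in% kept)     # boundary retained
  expect_false("hwe_bad" %in% kept)    # extreme HWE violation
  expect_true("normal" %in% kept)
  expect_false("id001" %in% qc$sample_ids)  # sample call rate 0.5
  expect_false(anyNA(qc$dosages))      # residual missing imputed
  att <- attr(qc, "attrition")
  expect_equal(att$step[1], "input")
  expect_equal(att$n_snps[1], 6)
})

test_that("HWE p-values agree with the chi-square reference at large counts", {
  # chi-square branch (n >= 1000)
  p <- hwe_test(400, 300, 300)
  e <- c(1000 * 0.45^2, 2 * 1000 * 0.45 * 0.55, 1000 * 0.55^2)
  x2 <- sum((c(400, 300, 300) - e)^2 / e)
  expect_equal(p, pchisq(x2, 1, lower.tail = FALSE))
  # exact branch: equilibrium-looking data is not rejected
  expect_gt(hwe_test(36, 48, 16), 0.5)
  # exact branch flags gross excess heterozygosity
  expect_lt(hwe_test(0, 200, 0), 1e-5)
})

test_that("A matrix reproduces textbook relationships", {
  two <- build_A(tibble::tibble(animal = 1:2, sire = 0, dam = 0))
  expect_equal(unname(two), diag(2))
  trio <- build_A(tibble::tibble(animal = 1:3, sire = c(0, 0, 1),
                                 dam = c(0, 0, 2)))
  expect_equal(unname(trio[3, ]), c(0.5, 0.5, 1))
  sibs <- build_A(tibble::tibble(animal = 1:4, sire = c(0, 0, 1, 1),
                                 dam = c(0, 0, 2, 2)))
  expect_equal(sibs["3", "4"], 0.5)
  # inbred offspring of parent-offspring mating has diagonal 1.25
  inbred <- build_A(tibble::tibble(animal = 1:3, sire = c(0, 1, 1),
                                   dam = c(0, 0, 2)))
  expect_equal(inbred["3", "3"], 1.25)
  # an animal that is its own ancestor is rejected
  expect_error(build_A(tibble::tibble(animal = 1:2, sire = c(2, 1),
                                      dam = c(0, 0))),
               class = "spectrakin_pedigree_error")
})

test_that("G follows the VanRaden construction on the one-SNP hand case", {
  # genotypes (0, 2): p = 0.5, centered (-1, 1), denominator 0.5
  M <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(build_G(M)), matrix(c(2, -2, -2, 2), 2))
})

test_that("G equals the naive double-loop computation", {
  set.seed(2)
  M <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50,
              dimnames = list(sprintf("s%02d", 1:10), NULL))
  G <- build_G(M)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  Z <- sweep(M, 2, 2 * p)
  G_naive <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    G_naive[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  }
  expect_equal(unname(G), G_naive, tolerance = 1e-10)
  # all-heterozygous at p = 0.5 still has positive denominator, G = 0
  Mh <- matrix(1, 4, 3, dimnames = list(letters[1:4], NULL))
  expect_equal(unname(build_G(Mh)), matrix(0, 4, 4))
  # monomorphic columns -> zero denominator error
  expect_error(build_G(matrix(2, 3, 4)), class = "spectrakin_kinship_error")
})

test_that("H inverse reduces to A inverse in the degenerate cases", {
  A <- build_A(tibble::tibble(animal = 1:5, sire = c(0, 0, 1, 1, 3),
                              dam = c(0, 0, 2, 2, 4)))
  Ainv <- chol2inv(chol(A))
  # G = A22 exactly -> correction cancels
  A22 <- A[4:5, 4:5]
  expect_equal(unname(build_Hinv(A, A22, A22)), unname(Ainv),
               tolerance = 1e-8)
  # no genotyped animals -> plain A inverse
  empty <- A[integer(0), integer(0), drop = FALSE]
  expect_equal(unname(build_Hinv(A, empty, empty)), unname(Ainv),
               tolerance = 1e-10)
})

test_that("kinship bundle is coherent on simulated data", {
  sb <- small_bundle()
  kin <- sb$bundle$kinship
  expect_true(isSymmetric(kin$Hinv, tol = 1e-8))
  expect_equal(kin$A22,
               kin$A[kin$genotyped_ids, kin$genotyped_ids])
  expect_true(all(diag(kin$A) >= 1))
  # mean diagonal of raw G near 1 under gene-dropped HWE-ish genotypes
  expect_equal(mean(diag(kin$G_raw)), 1, tolerance = 0.1)
})
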