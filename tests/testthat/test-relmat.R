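test_that("GRM matches a hand-computed example and basic expectations", {
  # 3 individuals x 2 SNPs, hand-set dosages
  X <- matrix(c(0L, 1L, 2L,
                2L, 1L, 1L), 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  g <- structure(X, class = c("genotype_matrix", "matrix", "array"))
  p <- colMeans(X) / 2                 # (0.5, 2/3)
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  G_hand <- tcrossprod(Z) / 2
  G <- compute_grm(g)
  expect_equal(G$values, G_hand, tolerance = 1e-12)
  expect_equal(G$n_snps_used, 2L)
  expect_true(isSymmetric(G$values))
})

test_that("duplicated individuals have identical GRM rows and diagonal", {
  set.seed(40)
  X <- matrix(rbinom(20 * 500, 2L, 0.4), 20, 500,
              dimnames = list(paste0("i", 1:20), paste0("s", 1:500)))
  X[2, ] <- X[1, ]   # duplicate
  g <- structure(X, class = c("genotype_matrix", "matrix", "array"))
  G <- compute_grm(g)$values
  expect_equal(G[1, 2], G[1, 1])
  expect_equal(G[2, 2], G[1, 1])
})

test_that("GRM diagonal and off-diagonal behave as expected in HWE founders", {
  ped <- simulate_pedigree(pedigree_spec(n_families = 100L, offspring = 0L, seed = 41L))
  g <- simulate_genotypes(ped, 20000L, maf_low = 0.1, seed = 42L)
  G <- compute_grm(g)$values
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
  expect_lt(abs(mean(G[upper.tri(G)])), 0.02)
})

test_that("GRM errors on monomorphic SNPs and is invariant to ordering", {
  X <- matrix(c(0L, 0L, 0L, 1L, 2L, 0L), 3, 2, dimnames = list(1:3, 1:2))
  g <- structure(X, class = c("genotype_matrix", "matrix", "array"))
  expect_error(compute_grm(g), "monomorphic")
  set.seed(43)
  Y <- matrix(rbinom(10 * 200, 2L, 0.3), 10, 200,
              dimnames = list(paste0("i", 1:10), paste0("s", 1:200)))
  gy <- structure(Y, class = c("genotype_matrix", "matrix", "array"))
  G1 <- compute_grm(gy)$values
  perm_snp <- sample(200); perm_ind <- sample(10)
  gy2 <- structure(Y[perm_ind, perm_snp],
                   class = c("genotype_matrix", "matrix", "array"))
  G2 <- compute_grm(gy2)$values
  expect_equal(G2, G1[perm_ind, perm_ind], tolerance = 1e-12)
})

test_that("K thresholding zeroes small off-diagonals and keeps the rest", {
  V <- matrix(c(1.01, 0.02, 0.30,
                0.02, 0.98, 0.049,
                0.30, 0.049, 1.00), 3, 3, dimnames = list(1:3, 1:3))
  G <- famvar:::new_relmat(V, "G", 100L)
  K <- threshold_grm(G, 0.05)$values
  expect_equal(K[1, 2], 0)
  expect_equal(K[2, 3], 0)
  expect_equal(K[1, 3], 0.30)
  expect_equal(diag(K), diag(V))
  # K = G at t = -Inf; K = diag(G) when t exceeds the max off-diagonal
  expect_equal(threshold_grm(G, -Inf)$values, V)
  Kd <- threshold_grm(G, 0.5)$values
  expect_equal(Kd, diag(diag(V)), ignore_attr = TRUE)
})

test_that("nonzero K pairs coincide with pedigree relatives on a simulated cohort", {
  ch <- small_cohort()
  K <- ch$K$values
  A <- pedigree_additive_matrix(ch$ped)[rownames(K), rownames(K)]
  rel <- A[upper.tri(A)] >= 0.25
  kk <- K[upper.tri(K)] > 0
  # every pedigree relative is captured; stragglers are sampling noise
  expect_gt(mean(kk[rel]), 0.99)
  expect_lt(mean(kk[!rel]), 0.01)
})

test_that("environment matrices implement the family/sibling/couple definitions", {
  ped <- simulate_pedigree(pedigree_spec(n_families = 1L, offspring = 2L, seed = 2L))
  Fm <- build_environment_matrix(ped, "family")$values
  Sm <- build_environment_matrix(ped, "sibling")$values
  Cm <- build_environment_matrix(ped, "couple")$values
  expect_equal(sum(Fm[upper.tri(Fm)]), 6)           # all pairs in one unit
  expect_equal(sum(Sm[upper.tri(Sm)]), 1)           # one offspring pair
  expect_equal(sum(Cm[upper.tri(Cm)]), 1)           # the parental couple
  kid <- ped$id[!is.na(ped$father)][1]
  expect_equal(Sm[as.character(kid), as.character(ped$father[ped$id == kid])], 0)
  expect_error(build_environment_matrix(ped, "household"))
})

test_that("half-siblings are not linked in S", {
  ped <- data.frame(id = 1:6,
                    father = c(NA, NA, NA, 1L, 1L, NA),
                    mother = c(NA, NA, NA, 2L, 3L, NA),
                    sex = c(1L, 0L, 0L, 1L, 0L, 1L),
                    spouse = c(2L, 1L, NA, NA, NA, NA))
  ped <- famvar:::as_pedigree(ped)
  Sm <- build_environment_matrix(ped, "sibling")$values
  expect_equal(Sm["4", "5"], 0)
  Fm <- build_environment_matrix(ped, "family")$values
  expect_equal(Fm["4", "5"], 0)   # different nuclear units
  expect_equal(Fm["4", "1"], 1)
  expect_equal(Fm["5", "1"], 1)   # father links to both units
})

test_that("S and C membership implies F membership; S count matches generator", {
  ch <- small_cohort()
  Fv <- ch$Fm$values; Sv <- ch$Sm$values; Cv <- ch$Cm$values
  expect_true(all(Fv[Sv == 1] == 1))
  expect_true(all(Fv[Cv == 1] == 1))
  cs <- pedigree_counts(ch$ped)
  expect_equal(sum(Sv) - nrow(Sv), 2 * cs$n_sib_pairs)
  expect_equal(sum(Cv) - nrow(Cv), 2 * cs$n_couples)
})

test_that("GCTA GRM files round-trip and agree with an independent parser", {
  set.seed(50)
  V <- crossprod(matrix(rnorm(100), 10))
  dimnames(V) <- list(paste0("i", 1:10), paste0("i", 1:10))
  M <- famvar:::new_relmat(V, "G", 123L)
  prefix <- withr::local_tempfile()
  write_grm(M, prefix)
  # element count: N(N+1)/2 float32 entries
  expect_equal(file.size(paste0(prefix, ".grm.bin")), 4 * 10 * 11 / 2)
  M2 <- read_grm(prefix)
  expect_lt(max(abs(M2$values - V)), 1e-6 * max(abs(V)))
  expect_equal(M2$n_snps_used, 123L)
  oracle <- read_grm_independent(prefix)
  expect_equal(M2$values, oracle, tolerance = 1e-12)
  # truncated file reports a format error
  writeBin(as.raw(1:7), paste0(prefix, ".grm.bin"))
  expect_error(read_grm(prefix), "mismatch")
})
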