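# fixed genotype fixture builders --------------------------------------------

clean_geno <- function(n = 6, m = 8, seed = 2) {
  set.seed(seed)
  codes <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.3, 0.4, 0.3)), n, m)
  genotype_matrix(codes)
}

test_that("qc_genotypes applies rules in order on constructed fixtures", {
  # no missingness, MAF 0.5 everywhere: untouched
  codes <- matrix(rep(c(0, 1, 2, 1), each = 3), 4, 3, byrow = TRUE)
  g <- genotype_matrix(rbind(codes, 2 - codes))
  out <- qc_genotypes(g)
  expect_equal(out$genotypes$codes, g$codes)
  expect_equal(nrow(out$report$removed_snps_callrate), 0)
  expect_equal(nrow(out$report$removed_snps_maf), 0)

  # 10x10: SNP 3 has call rate 0.8, SNP 7 has MAF 0.04 (retained boundary check)
  set.seed(4)
  codes <- matrix(1, 10, 10)
  codes[, seq(1, 9, 2)] <- sample(0:2, 50, replace = TRUE)
  codes[c(2, 5), 3] <- NA
  codes[, 7] <- 0; codes[1, 7] <- 1 # freq 1/20 = 0.05... make it 0.04 via missing
  codes[, 7] <- 0 # p = 0 would fail later; use 1 het of 10 -> maf 0.05 retained
  codes[1, 7] <- 1
  g <- genotype_matrix(codes)
  out <- qc_genotypes(g, maf = 0.06)
  expect_setequal(out$report$removed_snps_callrate$id, "M3")
  expect_true("M7" %in% out$report$removed_snps_maf$id)

  # MAF boundary: exactly at the threshold is retained
  codes <- cbind(rep(1, 10), c(1, rep(0, 9)))
  g <- genotype_matrix(codes)
  out <- qc_genotypes(g, maf = 0.05)
  expect_equal(ncol(out$genotypes$codes), 2)
})

test_that("Mendelian-conflict SNPs are removed against genotyped parents", {
  ped <- ped_from_text(
    c(animal = "P", sire = "0", dam = "0", year = "2000", sex = "M"),
    c(animal = "M", sire = "0", dam = "0", year = "2000", sex = "F"),
    c(animal = "O", sire = "P", dam = "M", year = "2002", sex = "M"))
  # SNP1: parent AA (2) vs offspring aa (0) -> opposite homozygotes
  codes <- rbind(P = c(2, 1, 1), M = c(1, 1, 0), O = c(0, 1, 1))
  g <- genotype_matrix(codes, animal_ids = c("P", "M", "O"))
  out <- qc_genotypes(g, ped, maf = 0)
  expect_equal(out$report$removed_snps_mendel$id, "M1")
  expect_equal(ncol(out$genotypes$codes), 2)
})

test_that("QC is idempotent", {
  set.seed(9)
  codes <- matrix(sample(c(0:2, NA), 200, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1)), 10, 20)
  g <- genotype_matrix(codes)
  once <- qc_genotypes(g)
  twice <- qc_genotypes(once$genotypes)
  expect_equal(twice$genotypes$codes, once$genotypes$codes)
  expect_equal(nrow(twice$report$removed_snps_callrate), 0)
  expect_equal(nrow(twice$report$removed_animals_callrate), 0)
  expect_equal(nrow(twice$report$removed_snps_maf), 0)
})

test_that("allele frequencies: pooled, missing-excluded, per breed", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1))
  expect_equal(unname(allele_frequencies(g)), 0.5)
  g <- genotype_matrix(matrix(c(2, 2, NA), 3, 1))
  expect_equal(unname(allele_frequencies(g)), 1)
  codes <- rbind(c(0, 2), c(1, 2), c(2, 0), c(2, 1))
  g <- genotype_matrix(codes, breed_of = stats::setNames(c("X", "X", "Y", "Y"),
                                                         paste0("A", 1:4)))
  pb <- allele_frequencies(g, "by_breed")
  expect_equal(unname(pb$X), c(1 / 4, 1))
  expect_equal(unname(pb$Y), c(1, 1 / 4))
  g_allmiss <- genotype_matrix(cbind(c(NA, NA), c(1, 1)))
  expect_error(allele_frequencies(g_allmiss), "non-missing")
})

test_that("VanRaden G: hand toy, centering identity, identical animals", {
  # 1 marker, p = 0.5, codes (0, 2): G = [[2,-2],[-2,2]]
  g <- genotype_matrix(matrix(c(0, 2), 2, 1))
  G <- build_G_vanraden1(g, p = 0.5)
  expect_equal(G, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  gg <- clean_geno(8, 40)
  G <- build_G_vanraden1(gg)
  expect_lt(max(abs(rowSums(G))), 1e-10) # self-frequency centering
  expect_lt(max(abs(G - t(G))), 1e-14)

  # duplicated animal rows: off-diagonal equals each one's diagonal
  codes <- rbind(a = c(0, 1, 2, 1, 0), b = c(0, 1, 2, 1, 0), c = c(2, 1, 0, 1, 2))
  g <- genotype_matrix(codes)
  G <- build_G_vanraden1(g, p = rep(0.5, 5))
  expect_equal(G["a", "b"], G["a", "a"])
})

test_that("breed-wise G reduces to VanRaden and matches a hand computation", {
  g <- clean_geno(6, 30, seed = 5)
  expect_lt(max(abs(build_G_breedwise(g) - build_G_vanraden1(g))), 1e-12)

  # two breeds with equal frequencies = pooled VanRaden at those frequencies
  codes <- clean_geno(6, 30, seed = 6)$codes
  bo <- stats::setNames(rep(c("X", "Y"), each = 3), rownames(codes))
  g2 <- genotype_matrix(codes, breed_of = bo)
  p <- rep(0.4, 30)
  expect_lt(max(abs(build_G_breedwise(g2, list(X = p, Y = p)) -
                    build_G_vanraden1(g2, p))), 1e-12)

  # 2 animals / 2 breeds / 2 markers: explicit formula evaluation
  codes <- rbind(i = c(0, 2), j = c(2, 1))
  g3 <- genotype_matrix(codes, breed_of = c(i = "X", j = "Y"))
  pX <- c(0.3, 0.6); pY <- c(0.7, 0.4)
  sX <- sum(2 * pX * (1 - pX)); sY <- sum(2 * pY * (1 - pY))
  expect_ij <- sum((c(0, 2) - 2 * pX) * (c(2, 1) - 2 * pY)) / sqrt(sX * sY)
  G <- build_G_breedwise(g3, list(X = pX, Y = pY))
  expect_equal(G["i", "j"], expect_ij, tolerance = 1e-12)
  expect_equal(G["i", "i"], sum((c(0, 2) - 2 * pX)^2) / sX, tolerance = 1e-12)

  # within-breed blocks equal per-breed VanRaden
  set.seed(8)
  codes <- matrix(sample(0:2, 10 * 50, replace = TRUE), 10, 50)
  bo <- stats::setNames(rep(c("X", "Y"), each = 5), paste0("A", 1:10))
  g4 <- genotype_matrix(codes, breed_of = bo)
  pb <- allele_frequencies(g4, "by_breed")
  Gbw <- build_G_breedwise(g4, pb)
  gX <- genotype_matrix(codes[1:5, ], animal_ids = paste0("A", 1:5))
  expect_lt(max(abs(Gbw[1:5, 1:5] - build_G_vanraden1(gX, pb$X))), 1e-12)
})

test_that("G05: zero het rows, hand toy, homozygous-alt diagonal", {
  g <- genotype_matrix(rbind(het = rep(1, 6), x = rep(2, 6)))
  G <- build_G_05(g)
  expect_equal(G["het", "het"], 0)
  expect_equal(unname(G["het", "x"]), 0)
  expect_equal(G["x", "x"], 2)
  g2 <- genotype_matrix(matrix(c(0, 2), 2, 1))
  expect_equal(build_G_05(g2), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
})

test_that("estimate_gamma matches population moments and degenerate cases", {
  p <- list(X = c(0.1, 0.4, 0.6, 0.9), Y = c(0.2, 0.3, 0.7, 0.8))
  mf <- estimate_gamma(p)
  m <- 4
  vX <- sum((p$X - mean(p$X))^2) / m
  cXY <- sum((p$X - mean(p$X)) * (p$Y - mean(p$Y))) / m
  expect_equal(mf$Gamma["X", "X"], 8 * vX, tolerance = 1e-12)
  expect_equal(mf$Gamma["X", "Y"], 8 * cXY, tolerance = 1e-12)

  same <- estimate_gamma(list(X = p$X, Y = p$X))
  expect_equal(same$Gamma["X", "X"], same$Gamma["X", "Y"], tolerance = 1e-10)
  flat <- estimate_gamma(list(X = rep(0.5, 5), Y = p$X[c(1:4, 1)]))
  expect_equal(flat$Gamma["X", "X"], 0, tolerance = 1e-10)
  expect_error(estimate_gamma(list(X = 0.5, Y = 0.5)), "2 markers")
})

test_that("blend_G arithmetic and guards", {
  set.seed(3)
  M <- crossprod(matrix(rnorm(25), 5))
  A22 <- crossprod(matrix(rnorm(25), 5))
  expect_equal(blend_G(M, A22, w = 1), M)
  expect_equal(blend_G(A22, A22, w = 0.3), A22)
  expect_equal(blend_G(M, A22, 0.95), 0.95 * M + 0.05 * A22)
  rownames(M) <- paste0("a", 1:5); rownames(A22) <- paste0("b", 1:5)
  expect_error(blend_G(M, A22), "order")
})

test_that("H inverse: degenerate reductions and the dense joint-form oracle", {
  s <- random_pedigree(30, n_founders = 8, seed = 21)
  Ainv <- build_A_inverse(s)
  expect_identical(build_H_inverse(Ainv, NULL, NULL, integer(0)), Ainv)

  A <- build_A(s)
  gids <- s$animal[seq(3, 27, 3)]
  A22 <- A[gids, gids]
  expect_lt(max(abs(as.matrix(build_H_inverse(Ainv, A22, A22, match(gids, s$animal)) - Ainv))), 1e-10)

  # simulated G: H inverse inverts the closed-form dense H
  set.seed(22)
  G <- A22 + 0.95 * crossprod(matrix(rnorm(length(gids)^2, 0, 0.15), length(gids)))
  Gb <- blend_G(G, A22)
  Hinv <- build_H_inverse(Ainv, A22, Gb, match(gids, s$animal))
  gi <- match(gids, s$animal)
  P <- matrix(0, nrow(s), length(gi))
  P[-gi, ] <- A[-gi, gi] %*% solve(A22)
  P[cbind(gi, seq_along(gi))] <- 1
  H <- A + P %*% (Gb - A22) %*% t(P)
  expect_lt(max(abs(as.matrix(Hinv) - solve(H))), 1e-6)
})

test_that("qc report serializes and genotype dialects round-trip", {
  set.seed(12)
  codes <- matrix(sample(c(0:2, NA), 120, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1)), 6, 20)
  bo <- stats::setNames(rep(c("X", "Y"), 3), paste0("A", 1:6))
  g <- genotype_matrix(codes, breed_of = bo)

  tmp <- withr::local_tempdir()
  write_plink(g, file.path(tmp, "gg"))
  g2 <- read_plink(file.path(tmp, "gg"))
  expect_equal(g2$codes, g$codes, ignore_attr = TRUE)
  expect_equal(unname(g2$breed_of), unname(g$breed_of))

  write_blupf90(g, file.path(tmp, "gg.txt"))
  g3 <- read_blupf90(file.path(tmp, "gg.txt"), breed_of = bo)
  expect_equal(unname(g3$codes), unname(g$codes))

  rep1 <- qc_genotypes(g)$report
  write_qc_report(rep1, file.path(tmp, "qc.csv"))
  expect_true(file.exists(file.path(tmp, "qc.csv")))
})
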