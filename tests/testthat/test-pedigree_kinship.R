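test_that("sort_pedigree orders parents before offspring and is stable", {
  # founders given in reverse id order keep the set, order by date then id
  p <- pedigree(c("C", "B", "A"), "0", "0", 2000, 1, "B1", "M")
  s <- sort_pedigree(p)
  expect_setequal(s$animal, c("A", "B", "C"))
  expect_equal(s$animal, c("A", "B", "C"))

  # offspring listed before its sire
  p <- pedigree(c("kid", "pa", "ma"), c("pa", "0", "0"), c("ma", "0", "0"),
                c(2005, 2000, 2000), 1, "B1", c("M", "M", "F"))
  s <- sort_pedigree(p)
  expect_lt(which(s$animal == "pa"), which(s$animal == "kid"))

  # random 50-animal pedigree: exhaustive parent-index check
  s <- random_pedigree(50, seed = 3)
  idx <- seq_len(nrow(s))
  si <- match(s$sire, s$animal); di <- match(s$dam, s$animal)
  expect_true(all(si[!is.na(si)] < idx[!is.na(si)]))
  expect_true(all(di[!is.na(di)] < idx[!is.na(di)]))
})

test_that("pedigree validation rejects cycles and unknown parents", {
  expect_error(pedigree(c("A", "B"), c("B", "A"), "0", 2000, 1, "B1", "M") |>
                 sort_pedigree(), "loop")
  expect_error(pedigree("A", "GHOST", "0", 2000, 1, "B1", "M"), "absent")
  expect_error(pedigree(c("A", "A"), "0", "0", 2000, 1, "B1", "M"), "duplicated")
})

test_that("inbreeding: founders zero, sire-daughter mating 0.25, matches diag(A) - 1", {
  founders <- sort_pedigree(pedigree(c("F1", "F2", "F3"), "0", "0", 2000, 1, "B1", "M"))
  expect_equal(compute_inbreeding(founders), c(F1 = 0, F2 = 0, F3 = 0))

  # sire mated to his own daughter -> offspring F = 0.25
  p <- ped_from_text(
    c(animal = "S", sire = "0", dam = "0", year = "2000", sex = "M"),
    c(animal = "D", sire = "0", dam = "0", year = "2000", sex = "F"),
    c(animal = "X", sire = "S", dam = "D", year = "2002", sex = "F"),
    c(animal = "Y", sire = "S", dam = "X", year = "2004", sex = "M"))
  f <- compute_inbreeding(p)
  expect_equal(unname(f["Y"]), 0.25)

  # random pedigree: recursive F equals tabular diag(A) - 1
  s <- random_pedigree(30, n_founders = 6, seed = 11)
  expect_gt(max(compute_inbreeding(s)), 0) # fixture actually carries inbreeding
  expect_lt(max(abs(diag(build_A(s)) - 1 - compute_inbreeding(s))), 1e-12)
})

test_that("build_A: textbook values on trios and full-sib matings", {
  expect_equal(build_A(sort_pedigree(pedigree(c("a", "b", "c"), "0", "0", 2000, 1, "B1", "M"))),
               diag(3), ignore_attr = TRUE)
  trio <- ped_from_text(
    c(animal = "S", sire = "0", dam = "0", year = "2000", sex = "M"),
    c(animal = "D", sire = "0", dam = "0", year = "2000", sex = "F"),
    c(animal = "O", sire = "S", dam = "D", year = "2002", sex = "M"))
  A <- build_A(trio)
  expect_equal(A["O", "S"], 0.5)
  expect_equal(A["O", "O"], 1)
  # full sibs mated: offspring self-relationship 1.25
  fs <- ped_from_text(
    c(animal = "S", sire = "0", dam = "0", year = "2000", sex = "M"),
    c(animal = "D", sire = "0", dam = "0", year = "2000", sex = "F"),
    c(animal = "B1x", sire = "S", dam = "D", year = "2002", sex = "M"),
    c(animal = "B2x", sire = "S", dam = "D", year = "2002", sex = "F"),
    c(animal = "K", sire = "B1x", dam = "B2x", year = "2004", sex = "M"))
  expect_equal(build_A(fs)["K", "K"], 1.25)
})

test_that("build_A agrees with the recursive-coancestry oracle and is PSD", {
  for (seed in 1:3) {
    s <- random_pedigree(80, n_founders = 12, seed = seed)
    A <- build_A(s)
    expect_lt(max(abs(A - kinship_oracle(s))), 1e-12)
    expect_lt(max(abs(A - t(A))), 1e-14)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("build_A_inverse matches dense inversion, including inbred pedigrees", {
  founders <- sort_pedigree(pedigree(c("a", "b"), "0", "0", 2000, 1, "B1", "M"))
  expect_equal(as.matrix(build_A_inverse(founders)), diag(2), ignore_attr = TRUE)

  trio <- ped_from_text(
    c(animal = "S", sire = "0", dam = "0", year = "2000", sex = "M"),
    c(animal = "D", sire = "0", dam = "0", year = "2000", sex = "F"),
    c(animal = "O", sire = "S", dam = "D", year = "2002", sex = "M"))
  expect_lt(max(abs(as.matrix(build_A_inverse(trio)) - solve(build_A(trio)))), 1e-12)

  s <- random_pedigree(200, n_founders = 20, seed = 5)
  Ainv <- build_A_inverse(s)
  expect_lt(max(abs(as.matrix(Ainv %*% build_A(s)) - diag(200))), 1e-8)
})

test_that("extract_A22 equals direct indexing of A", {
  s <- random_pedigree(60, n_founders = 10, seed = 7)
  A <- build_A(s)
  expect_equal(extract_A22(A, s$animal), A, ignore_attr = TRUE)
  one <- sort_pedigree(pedigree("solo", "0", "0", 2000, 1, "B1", "M"))
  expect_equal(extract_A22(one, "solo"), matrix(1, 1, 1), ignore_attr = TRUE)
  set.seed(1)
  ids <- sample(s$animal, 20)
  expect_lt(max(abs(extract_A22(s, ids) - A[ids, ids])), 1e-10)
  expect_error(extract_A22(s, "nope"), "unknown")
})

test_that("metafounder A(Gamma): degenerate, single-founder and cross-breed values", {
  s <- random_pedigree(40, n_founders = 8, seed = 9)
  mf0 <- metafounder_assignment("B1", matrix(0, 1, 1))
  expect_lt(max(abs(build_A_gamma(s, mf0) - build_A(s))), 1e-14)

  one <- sort_pedigree(pedigree("solo", "0", "0", 2000, 1, "B1", "M"))
  mf <- metafounder_assignment("B1", matrix(0.5, 1, 1))
  expect_equal(build_A_gamma(one, mf)["solo", "solo"], 1 + 0.5 * 0.5)

  two <- sort_pedigree(pedigree(c("x", "y"), "0", "0", 2000, 1, c("P", "Q"), "M"))
  Gm <- matrix(c(0.4, 0.2, 0.2, 0.6), 2, 2)
  mf2 <- metafounder_assignment(c("P", "Q"), Gm)
  AG <- build_A_gamma(two, mf2)
  expect_equal(AG["x", "y"], 0.2)
  expect_equal(AG["x", "x"], 1 + 0.5 * 0.4)
  expect_error(build_A_gamma(sort_pedigree(pedigree("z", "0", "0", 2000, 1, "R", "M")), mf2),
               "without a metafounder")
})

test_that("augmented metafounder inverse inverts the augmented A(Gamma)", {
  s <- random_pedigree(60, n_founders = 10, seed = 13)
  s$breed <- rep(c("P", "Q"), length.out = nrow(s))
  # keep matings within breed-agnostic pedigree but assign two metafounders
  mf <- metafounder_assignment(c("P", "Q"), matrix(c(0.5, 0.3, 0.3, 0.7), 2))
  AG <- build_A_gamma(s, mf, keep_metafounders = TRUE)
  AGinv <- build_A_gamma_inverse(s, mf)
  expect_lt(max(abs(as.matrix(AGinv %*% AG) - diag(nrow(AG)))), 1e-8)
})
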