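# small phenotype-table builder
toy_pheno <- function(animal, cg, farm = "f1", adg = NULL, wei = NULL, mus = NULL,
                      breed = "B1") {
  n <- length(animal)
  data.frame(animal = animal, breed = breed, sex = "M",
             birth_year = 2000, birth_month = 1,
             cg = cg, farm = farm,
             init_weight = seq(290, by = 5, length.out = n),
             age = seq(360, by = 2, length.out = n),
             adg = if (is.null(adg)) rep(NA_real_, n) else adg,
             wei = if (is.null(wei)) rep(NA_real_, n) else wei,
             mus = if (is.null(mus)) rep(NA_real_, n) else mus,
             stringsAsFactors = FALSE)
}

test_that("build_incidence: factor blocks, covariates, and missing-record masking", {
  ph <- toy_pheno(paste0("A", 1:4), cg = rep(c("c1", "c2"), each = 2),
                  adg = c(1.1, 1.2, 1.3, 1.4))
  spec <- model_spec("ADG", "pooled", "pedigree")
  bl <- build_incidence(ph, spec, paste0("A", 1:6))
  expect_equal(dim(bl$blocks[[1]]$X), c(4L, 2L)) # two CG columns, single farm dropped
  expect_equal(dim(bl$blocks[[1]]$Z), c(4L, 6L))
  expect_equal(Matrix::rowSums(bl$blocks[[1]]$Z), rep(1, 4), ignore_attr = TRUE)

  # WEI gains the initial-weight covariate column
  ph$wei <- c(500, 510, 520, 530)
  bl <- build_incidence(ph, model_spec(c("ADG", "WEI"), "pooled", "pedigree"),
                        paste0("A", 1:6))
  expect_true("init_weight" %in% colnames(bl$blocks[[2]]$X))
  expect_false("init_weight" %in% colnames(bl$blocks[[1]]$X))

  # masked records drop out of that trait's rows only
  ph$adg[2] <- NA
  bl <- build_incidence(ph, model_spec(c("ADG", "WEI"), "pooled", "pedigree"),
                        paste0("A", 1:6))
  expect_equal(length(bl$blocks[[1]]$y), 3L)
  expect_equal(length(bl$blocks[[2]]$y), 4L)
})

test_that("assemble_mme: hand-assembled single-record system and lambda invariance", {
  ph <- toy_pheno("A1", cg = "c1", adg = 2)
  spec <- model_spec("ADG", "pooled", "pedigree")
  bl <- build_incidence(ph, spec, "A1")
  K1 <- Matrix::Diagonal(1)
  s2u <- 0.4; s2e <- 1.6
  mme <- assemble_mme(bl, K1, variance_components(s2u, s2e))
  expect_equal(as.matrix(mme$LHS),
               matrix(c(1 / s2e, 1 / s2e, 1 / s2e, 1 / s2e + 1 / s2u), 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # only the variance ratio matters for the solutions
  set.seed(31)
  ped <- random_pedigree(40, seed = 31)
  ph <- toy_pheno(ped$animal[11:40], cg = rep(c("c1", "c2", "c3"), each = 10),
                  adg = rnorm(30, 1.5, 0.3))
  bl <- build_incidence(ph, spec, ped$animal)
  Ainv <- build_A_inverse(ped)
  r1 <- solve_mme(assemble_mme(bl, Ainv, variance_components(0.02, 0.05)))
  r2 <- solve_mme(assemble_mme(bl, Ainv, variance_components(0.2, 0.5)))
  expect_equal(r1$ebv, r2$ebv, tolerance = 1e-9)
})

test_that("diagonal G0 with disjoint records decouples into single-trait solves", {
  set.seed(32)
  ped <- random_pedigree(50, seed = 32)
  ids <- ped$animal
  ph <- toy_pheno(ids[21:50], cg = rep(c("c1", "c2"), 15),
                  adg = rnorm(30, 1.5, 0.3), wei = rnorm(30, 550, 50))
  Ainv <- build_A_inverse(ped)
  both <- build_incidence(ph, model_spec(c("ADG", "WEI"), "pooled", "pedigree"), ids)
  vc2 <- variance_components(diag(c(0.02, 900)), c(0.04, 2000))
  r_both <- solve_mme(assemble_mme(both, Ainv, vc2))
  one <- build_incidence(ph, model_spec("ADG", "pooled", "pedigree"), ids)
  r_one <- solve_mme(assemble_mme(one, Ainv, variance_components(0.02, 0.04)))
  expect_equal(r_both$ebv[, "ADG"], r_one$ebv[, "ADG"], tolerance = 1e-8)
})

test_that("solver: scalar shrinkage closed form and duplicate-record reweighting", {
  # one animal, known mean absorbed by its CG: u_hat = h2 (y - mu)
  # with a single record the CG absorbs everything; use 2 animals, one CG
  ph <- toy_pheno(c("A1", "A2"), cg = "c1", adg = c(2.0, 1.0))
  spec <- model_spec("ADG", "pooled", "pedigree")
  bl <- build_incidence(ph, spec, c("A1", "A2"))
  h2 <- 0.35
  vc <- variance_components(h2, 1 - h2)
  res <- solve_mme(assemble_mme(bl, Matrix::Diagonal(2), vc))
  # GLS oracle on the same system
  X <- matrix(1, 2); y <- c(2, 1)
  V <- h2 * diag(2) + (1 - h2) * diag(2)
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  u <- h2 * diag(2) %*% solve(V) %*% (y - X %*% b)
  expect_equal(unname(res$ebv[, 1]), as.vector(u), tolerance = 1e-10)

  # stacking each record twice acts exactly as doubling residual precision
  ph2 <- rbind(ph, ph)
  bl2 <- build_incidence(ph2, spec, c("A1", "A2"))
  res2 <- solve_mme(assemble_mme(bl2, Matrix::Diagonal(2), vc))
  blh <- build_incidence(ph, spec, c("A1", "A2"))
  resh <- solve_mme(assemble_mme(blh, Matrix::Diagonal(2),
                                 variance_components(h2, (1 - h2) / 2)))
  expect_equal(res2$ebv, resh$ebv, tolerance = 1e-10)
})

test_that("MME solutions match the dense GLS oracle on a simulated system", {
  cfg <- sim_config(breeds = "B1", h2_adg = 0.3, founders_per_breed = 30,
                    offspring_per_gen = 90, generations = 4, pheno_sex = "all",
                    genetic_model = "infinitesimal", seed = 41)
  ds <- simulate_dataset(cfg)
  spec <- model_spec("ADG", "pooled", "pedigree")
  ph <- ds$pheno[!is.na(ds$pheno$adg), ]
  bl <- build_incidence(ph, spec, ds$ped$animal)
  vc <- variance_components(ds$truth$sigma2_u[["ADG_B1"]], ds$truth$sigma2_e[["ADG_B1"]])
  res <- solve_mme(assemble_mme(bl, build_A_inverse(ds$ped), vc))
  A <- build_A(ds$ped)
  X <- as.matrix(bl$blocks[[1]]$X); Z <- as.matrix(bl$blocks[[1]]$Z); y <- bl$blocks[[1]]$y
  V <- vc$G0[1, 1] * Z %*% A %*% t(Z) + vc$R0 * diag(length(y))
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  uhat <- vc$G0[1, 1] * A %*% t(Z) %*% Vi %*% (y - X %*% bhat)
  expect_lt(max(abs(res$ebv[, 1] - uhat)), 1e-6)
})

test_that("pBLUP equals ssGBLUP built with zero genotyped animals", {
  cfg <- sim_config(breeds = "B1", h2_adg = 0.3, founders_per_breed = 20,
                    offspring_per_gen = 40, generations = 3, pheno_sex = "all",
                    genetic_model = "infinitesimal", seed = 43)
  ds <- simulate_dataset(cfg)
  spec <- model_spec("ADG", "pooled", "pedigree")
  ph <- ds$pheno[!is.na(ds$pheno$adg), ]
  bl <- build_incidence(ph, spec, ds$ped$animal)
  vc <- variance_components(ds$truth$sigma2_u[["ADG_B1"]], ds$truth$sigma2_e[["ADG_B1"]])
  Ainv <- build_A_inverse(ds$ped)
  Hinv <- build_H_inverse(Ainv, NULL, NULL, integer(0))
  rA <- solve_mme(assemble_mme(bl, Ainv, vc))
  rH <- solve_mme(assemble_mme(bl, Hinv, vc))
  expect_equal(rA$ebv, rH$ebv, tolerance = 1e-10)
})

test_that("rebasing zeroes the per-breed base-group means", {
  set.seed(33)
  ped <- random_pedigree(30, seed = 33)
  ped$breed <- rep(c("P", "Q"), 15)
  ebv <- matrix(rnorm(60), 30, 2, dimnames = list(ped$animal, c("t1", "t2")))
  res <- structure(list(ebv = ebv), class = "evaluation_result")
  base <- list(P = ped$animal[ped$breed == "P"][1:4],
               Q = ped$animal[ped$breed == "Q"][1:5])
  out <- rebase_ebv(res, ped, base)
  for (b in c("P", "Q")) {
    expect_lt(max(abs(colMeans(out$rebased[base[[b]], ]))), 1e-12)
  }
  # base group = all animals of a breed: that breed's overall mean is zero
  base_all <- split(ped$animal, ped$breed)
  out2 <- rebase_ebv(res, ped, base_all)
  expect_lt(max(abs(colMeans(out2$rebased[ped$breed == "P", ]))), 1e-12)
  # constant base EBVs shift everyone by -c
  ebv3 <- ebv; ebv3[base$P, 1] <- 0.7
  res3 <- structure(list(ebv = ebv3), class = "evaluation_result")
  out3 <- rebase_ebv(res3, ped, base)
  pp <- ped$breed == "P"
  expect_equal(out3$rebased[pp, 1], ebv3[pp, 1] - 0.7, ignore_attr = TRUE)
  expect_error(rebase_ebv(res, ped, list(P = "nope", Q = base$Q)), "empty base group")
})

test_that("metafounder variance scaling: k arithmetic and involution", {
  vc <- variance_components(diag(c(0.02, 0.03, 0.04)), c(0.05, 0.06, 0.07))
  expect_equal(attr(scale_variances_metafounder(vc, matrix(0, 3, 3)), "k"), 1)
  G <- matrix(0.3, 3, 3); diag(G) <- 0.6
  out <- scale_variances_metafounder(vc, G)
  expect_equal(attr(out, "k"), 0.9)
  expect_equal(out$G0, vc$G0 / 0.9)
  back <- variance_components(out$G0 * attr(out, "k"), out$R0)
  expect_equal(back$G0, vc$G0)
})

test_that("pooled multi-breed model with one breed equals the single-breed run", {
  cfg <- sim_config(breeds = "B1", h2_adg = 0.3, founders_per_breed = 20,
                    offspring_per_gen = 60, generations = 3, markers = 200, seed = 47)
  ds <- simulate_dataset(cfg)
  rSB <- run_scenario("SB_pBLUP", ds, control = list(bootstrap_B = 50))
  rMB <- run_scenario("STMB_pBLUP", ds, control = list(bootstrap_B = 50))
  expect_equal(rSB$metrics$acc_p, rMB$metrics$acc_p, tolerance = 1e-10)
  expect_equal(rSB$metrics$b_p, rMB$metrics$b_p, tolerance = 1e-10)
})
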