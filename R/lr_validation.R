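#' Truncate phenotypes at a cutoff birth date
#'
#' Phenotype values of animals born on or after the cutoff (half-open
#' comparison on year and month) are set to missing for all traits;
#' pedigree and genotypes are untouched. This produces the "partial"
#' dataset of the LR forward validation.
#'
#' @param pheno phenotype table with `birth_year` and `birth_month`.
#' @param cutoff list or vector with `year` and `month`.
#' @return The masked phenotype table.
#' @export
make_partial_dataset <- function(pheno, cutoff) {
  cutoff <- as.list(stats::setNames(as.integer(unlist(cutoff)[1:2]), c("year", "month")))
  after <- (pheno$birth_year > cutoff$year) |
    (pheno$birth_year == cutoff$year & pheno$birth_month >= cutoff$month)
  masked <- pheno
  tcols <- intersect(c("adg", "wei", "mus"), names(pheno))
  masked[after, tcols] <- NA
  if (all(is.na(masked[, tcols]))) stop("cutoff masks every phenotype; nothing left to fit")
  masked
}

#' Define the LR focal group
#'
#' Per breed: male animals with a whole-data phenotype born on or after the
#' cutoff.
#'
#' @param ped a `pedigree` (source of sex, breed, birth date).
#' @param pheno whole-data phenotype table.
#' @param cutoff list/vector with `year` and `month`.
#' @return Named list breed -> character ids.
#' @export
define_focal_group <- function(ped, pheno, cutoff) {
  cutoff <- as.list(stats::setNames(as.integer(unlist(cutoff)[1:2]), c("year", "month")))
  tcols <- intersect(c("adg", "wei", "mus"), names(pheno))
  has_ph <- pheno$animal[rowSums(!is.na(pheno[, tcols, drop = FALSE])) > 0]
  after <- (ped$birth_year > cutoff$year) |
    (ped$birth_year == cutoff$year & ped$birth_month >= cutoff$month)
  sel <- after & ped$sex == "M" & ped$animal %in% has_ph
  out <- split(ped$animal[sel], ped$breed[sel])
  empty <- setdiff(unique(ped$breed), names(out))
  if (length(empty)) stop("empty focal group for breed(s): ", paste(empty, collapse = ", "))
  out
}

lr_stats <- function(w, p, sigma2_u, f_bar) {
  cv <- stats::cov(w, p)
  vp <- stats::var(p)
  acc <- if (cv < 0) NA_real_ else sqrt(cv / ((1 - f_bar) * sigma2_u))
  list(acc_p = acc, b_p = cv / vp, delta_p = (mean(p) - mean(w)) / sqrt(sigma2_u))
}

#' LR validation metrics
#'
#' Compares partial (truncated-data) with whole-data EBVs of the focal
#' group: accuracy `acc_p = sqrt(cov(u_w, u_p) / ((1 - Fbar) sigma2_u))`,
#' dispersion `b_p = cov(u_w, u_p) / var(u_p)` (expectation 1), and level
#' bias `Delta_p = (mean(u_p) - mean(u_w)) / sqrt(sigma2_u)` in genetic
#' standard deviations (expectation 0). Covariances are n-1 sample
#' statistics over the focal group. A negative covariance makes the
#' accuracy undefined (reported `NA` with a warning); the other metrics are
#' still returned.
#'
#' @param ebv_whole,ebv_partial named numeric vectors of EBVs covering the
#'   focal ids (one effective trait).
#' @param focal_ids character ids of the focal group.
#' @param sigma2_u additive genetic variance (> 0) used for scaling.
#' @param f_bar mean inbreeding coefficient of the focal group, in
#'   `[0, 1)`.
#' @return An object of class `lr_metrics`.
#' @export
compute_lr_metrics <- function(ebv_whole, ebv_partial, focal_ids, sigma2_u, f_bar = 0) {
  focal_ids <- as.character(focal_ids)
  if (!all(focal_ids %in% names(ebv_whole)) || !all(focal_ids %in% names(ebv_partial))) {
    stop("both evaluations must cover every focal animal")
  }
  if (sigma2_u <= 0) stop("sigma2_u must be positive")
  if (f_bar < 0 || f_bar >= 1) stop("f_bar must lie in [0, 1)")
  w <- ebv_whole[focal_ids]
  p <- ebv_partial[focal_ids]
  st <- lr_stats(w, p, sigma2_u, f_bar)
  if (is.na(st$acc_p)) warning("negative cov(u_w, u_p); acc_p undefined for this group")
  structure(list(acc_p = st$acc_p, b_p = st$b_p, delta_p = st$delta_p,
                 n_focal = length(focal_ids), sigma2_u = sigma2_u, f_bar = f_bar),
            class = "lr_metrics")
}

#' Bootstrap standard errors of the LR metrics
#'
#' Focal animals are resampled with replacement (their whole and partial
#' EBVs jointly) `B` times; each metric is recomputed per replicate and its
#' standard deviation over replicates reported as the SE. Replicates in
#' which the resampled partial EBVs are degenerate (zero variance) are
#' skipped and counted.
#'
#' @inheritParams compute_lr_metrics
#' @param B number of bootstrap samples (default 10000).
#' @param seed RNG seed.
#' @return List with `acc_p_se`, `b_p_se`, `delta_p_se`, and the number of
#'   skipped replicates.
#' @export
bootstrap_se <- function(ebv_whole, ebv_partial, focal_ids, sigma2_u, f_bar = 0,
                         B = 10000, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  focal_ids <- as.character(focal_ids)
  w <- ebv_whole[focal_ids]
  p <- ebv_partial[focal_ids]
  n <- length(focal_ids)
  set.seed(seed)
  acc <- bb <- dd <- rep(NA_real_, B)
  skipped <- 0L
  for (r in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pr <- p[idx]
    if (stats::var(pr) == 0) {
      skipped <- skipped + 1L
      next
    }
    st <- lr_stats(w[idx], pr, sigma2_u, f_bar)
    acc[r] <- st$acc_p; bb[r] <- st$b_p; dd[r] <- st$delta_p
  }
  sd0 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x)
  }
  list(acc_p_se = sd0(acc), b_p_se = sd0(bb), delta_p_se = sd0(dd), skipped = skipped)
}

#' Replicate simulation study of the LR statistics
#'
#' Simulates an unselected, randomly mating population `n_rep` times; for
#' each replicate runs whole and partial pedigree BLUP evaluations with the
#' generator's true variance components and a birth-date cutoff masking
#' the last generation, and computes the LR statistics over the focal
#' group (phenotyped males born on/after the cutoff), plus the empirical
#' accuracy `cor(u_p, u_true)/sqrt(1 - Fbar)` against the simulated true
#' breeding values. Under random mating and correct variance components
#' the dispersion statistic has expectation 1 and the level bias
#' expectation 0.
#'
#' @param n_rep number of replicates.
#' @param cfg a single-breed [sim_config()] (its `seed` is replaced per
#'   replicate).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return Data frame with one row per replicate: `acc_p`, `b_p`,
#'   `delta_p`, `acc_emp`, `n_focal`.
#' @export
lr_simulation_study <- function(n_rep = 30,
                                cfg = sim_config(breeds = "B1", h2_adg = 0.3,
                                                 generations = 5,
                                                 founders_per_breed = 150,
                                                 offspring_per_gen = 750,
                                                 genetic_model = "infinitesimal",
                                                 pheno_sex = "M"),
                                seed = 1) {
  spec <- model_spec(traits = "ADG", breed_handling = "pooled",
                     relationship = "pedigree", name = "SB_pBLUP")
  cutoff <- sim_default_cutoff(cfg)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg$seed <- seed + r
    ds <- simulate_dataset(cfg)
    ped <- ds$ped
    pheno <- ds$pheno[!is.na(ds$pheno$adg), , drop = FALSE]
    vc <- variance_components(ds$truth$sigma2_u["ADG_B1"],
                              ds$truth$sigma2_e["ADG_B1"])
    names(vc$G0) <- NULL
    Ainv <- build_A_inverse(ped)
    fit <- function(ph) {
      blocks <- build_incidence(ph, spec, ped$animal)
      solve_mme(assemble_mme(blocks, Ainv, vc))
    }
    whole <- fit(pheno)
    partial <- fit(make_partial_dataset(pheno, cutoff))
    focal <- define_focal_group(ped, pheno, cutoff)[[1]]
    f_bar <- mean(compute_inbreeding(ped)[focal])
    w <- stats::setNames(whole$ebv[, 1], rownames(whole$ebv))
    p <- stats::setNames(partial$ebv[, 1], rownames(partial$ebv))
    met <- compute_lr_metrics(w, p, focal, vc$G0[1, 1], f_bar)
    u_true <- true_bv_for(ds$truth, ped)[focal]
    out[[r]] <- data.frame(
      acc_p = met$acc_p, b_p = met$b_p, delta_p = met$delta_p,
      acc_emp = stats::cor(p[focal], u_true) / sqrt(1 - f_bar),
      n_focal = length(focal))
  }
  do.call(rbind, out)
}

#' Write LR metrics for a set of scenarios/breeds as CSV
#'
#' One row per scenario and breed: `acc_p (SE), b_p (SE), delta_p (SE)`.
#'
#' @param rows data frame with columns `scenario`, `breed`, `acc_p`,
#'   `acc_p_se`, `b_p`, `b_p_se`, `delta_p`, `delta_p_se`.
#' @param path output CSV path.
#' @export
write_lr_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
}
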