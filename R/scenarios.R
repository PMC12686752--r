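#' The ten evaluation scenarios
#'
#' Feature matrix of the implemented scenarios: whether the relationship
#' matrix uses genotypes (single-step) or pedigree only, whether breeds are
#' evaluated jointly, whether ADG is modelled as a different correlated
#' trait per breed, whether WEI and MUS enter as correlated traits, and
#' which genomic-matrix variant is used.
#'
#' @return A data frame with one row per scenario.
#' @export
scenario_table <- function() {
  data.frame(
    scenario = c("SB_pBLUP", "SB_ssGBLUP", "STMB_pBLUP", "STMB_ssGBLUP",
                 "MTMB_ssGBLUP", "MTMB_W_ssGBLUP", "MTMB_MF_ssGBLUP",
                 "SB_3pheno_pBLUP", "SB_3pheno_ssGBLUP", "MB_3pheno_ssGBLUP"),
    genomic = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    multibreed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    adg_different_trait = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    wei_mus = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    G_variant = c(NA, "vanraden1", NA, "vanraden1", "vanraden1", "breedwise",
                  "metafounder", NA, "vanraden1", "vanraden1"),
    stringsAsFactors = FALSE)
}

scenario_features <- function(name) {
  tab <- scenario_table()
  row <- tab[tab$scenario == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown scenario: ", name, "; see scenario_table()")
  as.list(row)
}

# model_spec for a scenario row
scenario_model_spec <- function(feat) {
  model_spec(
    traits = if (feat$wei_mus) c("ADG", "WEI", "MUS") else "ADG",
    breed_handling = if (feat$adg_different_trait) "correlated_traits"
                     else if (feat$multibreed) "pooled" else "separate",
    relationship = if (feat$genomic) "single_step" else "pedigree",
    G_variant = if (is.na(feat$G_variant)) "vanraden1" else feat$G_variant,
    name = feat$scenario)
}

# true/assumed variance components for a scenario from simulation truth
scenario_true_vc <- function(truth, spec, breeds) {
  g0 <- truth$G0_target
  s2e <- truth$sigma2_e
  if (spec$breed_handling == "correlated_traits") {
    labs <- paste0("ADG_", sort(breeds))
    variance_components(g0[labs, labs], s2e[labs])
  } else if (length(spec$traits) == 3L) {
    if (length(breeds) == 1L) {
      labs <- paste(c("ADG", "WEI", "MUS"), breeds, sep = "_")
      variance_components(g0[labs, labs], s2e[labs])
    } else {
      blocks <- lapply(breeds, function(b) {
        labs <- paste(c("ADG", "WEI", "MUS"), b, sep = "_")
        list(G = g0[labs, labs], R = s2e[labs])
      })
      variance_components(Reduce(`+`, lapply(blocks, `[[`, "G")) / length(breeds),
                          Reduce(`+`, lapply(blocks, `[[`, "R")) / length(breeds))
    }
  } else {
    labs <- paste0("ADG_", breeds)
    variance_components(mean(diag(g0)[match(labs, rownames(g0))]),
                        mean(s2e[labs]))
  }
}

# relationship-inverse (and metadata) for one scenario on one pedigree
scenario_kinverse <- function(spec, ped, geno, mf = NULL) {
  f <- compute_inbreeding(ped)
  A_inv <- build_A_inverse(ped, f)
  if (spec$relationship == "pedigree" || is.null(geno) || nrow(geno$codes) == 0L) {
    return(list(K_inv = A_inv, ids = ped$animal, mf = NULL, k = 1))
  }
  gids <- intersect(ped$animal, geno$animal_ids)
  gsub <- genotype_matrix(geno$codes[gids, , drop = FALSE], breed_of = geno$breed_of[gids])
  if (spec$G_variant == "metafounder") {
    if (is.null(mf)) mf <- estimate_gamma(allele_frequencies(gsub, "by_breed"))
    AGinv <- build_A_gamma_inverse(ped, mf)
    nb <- attr(AGinv, "n_metafounders")
    AG <- build_A_gamma(ped, mf, keep_metafounders = FALSE)
    A22g <- AG[gids, gids, drop = FALSE]
    G <- build_G_05(gsub)
    Gb <- blend_G(G, A22g)
    H_inv <- build_H_inverse(AGinv, A22g, Gb, nb + match(gids, ped$animal))
    return(list(K_inv = H_inv, ids = rownames(AGinv), mf = mf, n_mf = nb))
  }
  A22 <- extract_A22(ped, gids)
  G <- if (spec$G_variant == "breedwise") build_G_breedwise(gsub) else build_G_vanraden1(gsub)
  Gb <- blend_G(G, A22)
  H_inv <- build_H_inverse(A_inv, A22, Gb, match(gids, ped$animal))
  list(K_inv = H_inv, ids = ped$animal, mf = NULL)
}

# one whole-vs-partial evaluation given K inverse and VC
evaluate_whole_partial <- function(pheno, spec, kin, vc, cutoff, ped, base_ids) {
  fit1 <- function(ph) {
    blocks <- build_incidence(ph[rowSums(!is.na(ph[, intersect(c("adg", "wei", "mus"),
                                                               names(ph)), drop = FALSE])) > 0, ,
                                 drop = FALSE], spec, kin$ids)
    res <- solve_mme(assemble_mme(blocks, kin$K_inv, vc))
    rebase_ebv(res, ped, base_ids)
  }
  whole <- fit1(pheno)
  partial <- fit1(make_partial_dataset(pheno, cutoff))
  list(whole = whole, partial = partial)
}

# EBV column relevant for a breed's ADG under a model spec
adg_column <- function(spec, breed) {
  if (spec$breed_handling == "correlated_traits") paste0("ADG_", breed) else "ADG"
}

#' Run one scenario end to end
#'
#' Executes the scenario's stage chain on a simulated (or read) dataset:
#' genotype QC, relationship-matrix construction, variance components
#' (true values from the generator by default, or Gibbs VCE when a chain
#' is supplied), whole and partial evaluations, rebasing, and per-breed LR
#' validation with bootstrap standard errors.
#'
#' @param name scenario name (see [scenario_table()]).
#' @param dataset a `sim_dataset` (or list with `ped`, `geno`, `pheno`,
#'   `truth`, `cfg`).
#' @param control list: `cutoff` (default: birth of the simulated last
#'   generation), `base_years` (default: the two earliest phenotyped birth
#'   years), `vce` (`NULL` for generator-truth variance components, or a
#'   [chain_config()]), `bootstrap_B` (default 1000), `seed`.
#' @return A list of class `scenario_result`: per-breed LR metric table,
#'   whole/partial `evaluation_result`s per fitted unit, the variance
#'   components used, and the scenario features.
#' @export
run_scenario <- function(name, dataset, control = list()) {
  feat <- scenario_features(name)
  spec <- scenario_model_spec(feat)
  ped <- dataset$ped
  pheno <- dataset$pheno
  cutoff <- control$cutoff
  if (is.null(cutoff)) cutoff <- sim_default_cutoff(dataset$cfg)
  B <- if (is.null(control$bootstrap_B)) 1000 else control$bootstrap_B
  seed <- if (is.null(control$seed)) 1L else control$seed
  tcols <- intersect(c("adg", "wei", "mus"), names(pheno))
  ph_ids <- pheno$animal[rowSums(!is.na(pheno[, tcols, drop = FALSE])) > 0]
  base_years <- control$base_years
  if (is.null(base_years)) {
    yrs <- sort(unique(ped$birth_year[ped$animal %in% ph_ids]))
    base_years <- yrs[seq_len(min(2L, length(yrs)))]
  }
  breeds <- sort(unique(ped$breed))
  f_all <- compute_inbreeding(ped)
  units <- if (spec$breed_handling == "separate") breeds else list(breeds)

  rows <- list()
  fits <- list()
  vcs <- list()
  for (un in units) {
    un_breeds <- unlist(un)
    ped_u <- ped[ped$breed %in% un_breeds, , drop = FALSE]
    attr(ped_u, "sorted") <- TRUE
    pheno_u <- pheno[pheno$breed %in% un_breeds & pheno$animal %in% ph_ids, , drop = FALSE]
    # QC runs within the evaluated unit (within breed for single-breed
    # scenarios, across breeds pooled for multi-breed ones)
    geno_u <- NULL
    if (feat$genomic && !is.null(dataset$geno)) {
      ids <- dataset$geno$animal_ids[dataset$geno$breed_of %in% un_breeds]
      if (length(ids)) {
        graw <- genotype_matrix(dataset$geno$codes[ids, , drop = FALSE],
                                breed_of = dataset$geno$breed_of[ids])
        geno_u <- qc_genotypes(graw, ped_u)$genotypes
      }
    }
    kin <- scenario_kinverse(spec, ped_u, geno_u)

    if (inherits(control$vce, "chain_config")) {
      pheno_vce <- subset_for_vce(pheno_u, if (is.null(geno_u)) character(0) else geno_u$animal_ids, name)
      blocks_vce <- build_incidence(pheno_vce, spec, kin$ids)
      store <- run_gibbs(blocks_vce, kin$K_inv, control$vce)
      ps <- summarize_posterior(store)
      Tn <- store$n_traits
      G0 <- matrix(0, Tn, Tn)
      G0[lower.tri(G0, diag = TRUE)] <- ps$components$mean[seq_len(Tn * (Tn + 1) / 2)]
      G0 <- G0 + t(G0) - diag(diag(G0), Tn)
      vc <- variance_components(G0, ps$components$mean[Tn * (Tn + 1) / 2 + seq_len(Tn)])
      posterior <- ps
    } else {
      vc <- scenario_true_vc(dataset$truth, spec, un_breeds)
      posterior <- NULL
    }
    if (spec$G_variant == "metafounder" && !is.null(kin$mf)) {
      vc <- scale_variances_metafounder(vc, kin$mf)
    }
    base_ids <- define_base_group(ped_u, pheno_u, base_years)
    fit <- evaluate_whole_partial(pheno_u, spec, kin, vc, cutoff, ped_u, base_ids)
    focal <- define_focal_group(ped_u, pheno_u, cutoff)

    for (b in un_breeds) {
      col <- adg_column(spec, b)
      t_idx <- match(col, colnames(fit$whole$ebv))
      w <- stats::setNames(fit$whole$rebased[, t_idx], rownames(fit$whole$rebased))
      p <- stats::setNames(fit$partial$rebased[, t_idx], rownames(fit$partial$rebased))
      ids <- focal[[b]]
      s2u <- scenario_sigma2u_for_breed(vc, spec, b, un_breeds)
      fb <- mean(f_all[ids])
      met <- compute_lr_metrics(w, p, ids, s2u, fb)
      se <- bootstrap_se(w, p, ids, s2u, fb, B = B, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = name, breed = b, acc_p = met$acc_p, acc_p_se = se$acc_p_se,
        b_p = met$b_p, b_p_se = se$b_p_se, delta_p = met$delta_p,
        delta_p_se = se$delta_p_se, n_focal = met$n_focal, f_bar = fb,
        sigma2_u = s2u, stringsAsFactors = FALSE)
    }
    key <- paste(un_breeds, collapse = "+")
    fits[[key]] <- fit
    vcs[[key]] <- list(vc = vc, posterior = posterior)
  }
  structure(list(name = name, features = feat, metrics = do.call(rbind, rows),
                 fits = fits, vc = vcs, cutoff = cutoff, base_years = base_years),
            class = "scenario_result")
}

# the additive genetic variance relevant to a breed's ADG under a spec
scenario_sigma2u_for_breed <- function(vc, spec, breed, breeds) {
  if (spec$breed_handling == "correlated_traits") {
    lab <- paste0("ADG_", breed)
    i <- match(lab, colnames(vc$G0))
    if (is.na(i)) i <- match(breed, sort(breeds))
    vc$G0[i, i]
  } else {
    vc$G0[1, 1] # ADG is the first effective trait in every other layout
  }
}

#' Compare scenario results on one dataset
#'
#' Per-breed differences of acc_p, b_p and delta_p between two scenario
#' results, with dispersion values outside the 15% acceptability band
#' around 1 flagged.
#'
#' @param a,b `scenario_result`s computed on the same dataset.
#' @return Data frame of per-breed deltas (`a - b`) with a
#'   `dispersion_flag` column marking |b_p - 1| > 0.15 in either scenario.
#' @export
compare_scenarios <- function(a, b) {
  ma <- a$metrics; mb <- b$metrics
  if (!identical(sort(ma$breed), sort(mb$breed))) stop("scenario results cover different breeds")
  mb <- mb[match(ma$breed, mb$breed), , drop = FALSE]
  data.frame(
    breed = ma$breed,
    d_acc_p = ma$acc_p - mb$acc_p,
    d_b_p = ma$b_p - mb$b_p,
    d_delta_p = ma$delta_p - mb$delta_p,
    acc_p_se_a = ma$acc_p_se, acc_p_se_b = mb$acc_p_se,
    dispersion_flag = abs(ma$b_p - 1) > 0.15 | abs(mb$b_p - 1) > 0.15,
    stringsAsFactors = FALSE)
}

#' Flag dispersion outside the acceptability band
#' @param b_p dispersion statistic(s).
#' @param band half-width of the acceptable band around 1 (default 0.15).
#' @return Logical vector, `TRUE` where dispersion is outside the band.
#' @export
dispersion_flagged <- function(b_p, band = 0.15) abs(b_p - 1) > band
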