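#' Simulation configuration for multi-breed performance-test data
#'
#' Defaults emulate a three-breed beef performance-test design: three
#' breeds with drift-diverged allele frequencies, discrete generations of
#' within-breed random mating, station contemporary groups (breed x birth
#' month x birth year, with four intake months per year), phenotypes on
#' young bulls only, and marker-effect genetics giving per-breed ADG
#' heritabilities of 0.25/0.18/0.35 and an ADG-WEI genetic correlation of
#' 0.95.
#'
#' @param breeds breed labels.
#' @param markers number of biallelic markers.
#' @param divergence drift variance multiplier between ancestral and breed
#'   allele frequencies (`Var = d p (1 - p)`).
#' @param generations total discrete generations including founders.
#' @param founders_per_breed,offspring_per_gen,n_sires pedigree structure
#'   per breed and generation.
#' @param h2_adg named per-breed heritability of ADG.
#' @param h2_wei,h2_mus heritabilities of the companion traits.
#' @param rg_between genetic correlation of ADG across breeds (scalar or
#'   breed x breed matrix).
#' @param cor_adg_wei,cor_adg_mus,cor_wei_mus within-breed genetic
#'   correlations (scalar or named per breed).
#' @param mean_adg,mean_wei,mean_mus named per-breed trait means.
#' @param sd_adg,sd_wei,sd_mus phenotypic standard deviations.
#' @param farms_per_breed number of farm-of-origin levels per breed.
#' @param cg_sd_frac,farm_sd_frac contemporary-group and farm effect SDs as
#'   fractions of the phenotypic SD.
#' @param genotyping_prop proportion of phenotyped males genotyped.
#' @param pheno_sex `"M"` (bulls only) or `"all"`.
#' @param start_year,year_gap,birth_months birth-date layout: generation g
#'   is born in `[start_year + g*year_gap, start_year + (g+1)*year_gap)`,
#'   in the given intake months.
#' @param genetic_model `"marker"` (gene-dropped marker effects) or
#'   `"infinitesimal"` (pedigree-based, for pedigree-only studies).
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(breeds = c("MAR", "CHI", "ROM"),
                       markers = 2000,
                       divergence = 0.05,
                       generations = 5,
                       founders_per_breed = 120,
                       offspring_per_gen = 300,
                       n_sires = 25,
                       h2_adg = c(MAR = 0.25, CHI = 0.18, ROM = 0.35),
                       h2_wei = 0.30,
                       h2_mus = 0.28,
                       rg_between = 0.4,
                       cor_adg_wei = 0.95,
                       cor_adg_mus = c(MAR = 0.35, CHI = 0.17, ROM = 0.59),
                       cor_wei_mus = c(MAR = 0.44, CHI = 0.18, ROM = 0.43),
                       mean_adg = c(MAR = 1.593, CHI = 1.686, ROM = 1.553),
                       mean_wei = c(MAR = 539, CHI = 578, ROM = 527),
                       mean_mus = c(MAR = 397, CHI = 371, ROM = 375),
                       sd_adg = 0.24, sd_wei = 57, sd_mus = 62,
                       farms_per_breed = 15,
                       cg_sd_frac = 0.3, farm_sd_frac = 0.2,
                       genotyping_prop = 0.6,
                       pheno_sex = "M",
                       start_year = 1988, year_gap = 7,
                       birth_months = c(1, 4, 7, 10),
                       genetic_model = c("marker", "infinitesimal"),
                       seed = 1) {
  genetic_model <- match.arg(genetic_model)
  nb <- length(breeds)
  expand <- function(x) {
    if (!is.null(names(x)) && all(breeds %in% names(x))) return(x[breeds])
    if (length(x) == nb) return(stats::setNames(as.numeric(x), breeds))
    stats::setNames(rep(mean(x), nb), breeds)
  }
  h2_adg <- expand(h2_adg); h2_wei <- expand(h2_wei); h2_mus <- expand(h2_mus)
  cor_adg_wei <- expand(cor_adg_wei); cor_adg_mus <- expand(cor_adg_mus)
  cor_wei_mus <- expand(cor_wei_mus)
  mean_adg <- expand(mean_adg); mean_wei <- expand(mean_wei); mean_mus <- expand(mean_mus)
  if (any(c(h2_adg, h2_wei, h2_mus) <= 0) || any(c(h2_adg, h2_wei, h2_mus) >= 1)) {
    stop("heritabilities must lie in (0, 1)")
  }
  if (divergence < 0) stop("divergence must be non-negative")
  if (is.matrix(rg_between)) {
    RG <- rg_between
  } else {
    RG <- matrix(rg_between, nb, nb)
    diag(RG) <- 1
  }
  dimnames(RG) <- list(breeds, breeds)
  structure(list(
    breeds = breeds, markers = as.integer(markers), divergence = divergence,
    generations = as.integer(generations),
    founders_per_breed = as.integer(founders_per_breed),
    offspring_per_gen = as.integer(offspring_per_gen), n_sires = as.integer(n_sires),
    h2_adg = h2_adg, h2_wei = h2_wei, h2_mus = h2_mus, rg_between = RG,
    cor_adg_wei = cor_adg_wei, cor_adg_mus = cor_adg_mus, cor_wei_mus = cor_wei_mus,
    mean_adg = mean_adg, mean_wei = mean_wei, mean_mus = mean_mus,
    sd_adg = sd_adg, sd_wei = sd_wei, sd_mus = sd_mus,
    farms_per_breed = as.integer(farms_per_breed),
    cg_sd_frac = cg_sd_frac, farm_sd_frac = farm_sd_frac,
    genotyping_prop = genotyping_prop, pheno_sex = pheno_sex,
    start_year = as.integer(start_year), year_gap = as.integer(year_gap),
    birth_months = as.integer(birth_months),
    genetic_model = genetic_model, seed = as.integer(seed)),
    class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose fields override [sim_config()] defaults.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}

#' Default validation cutoff: birth of the last generation
#' @param cfg a `sim_config`.
#' @return List with `year` and `month`.
#' @export
sim_default_cutoff <- function(cfg) {
  list(year = cfg$start_year + (cfg$generations - 1L) * cfg$year_gap, month = 1L)
}

#' Simulate breed allele frequencies by drift from a common ancestor
#'
#' Ancestral frequencies are Uniform(0.1, 0.9); each breed drifts
#' independently with variance `d p (1 - p)` and is clipped to
#' (0.02, 0.98).
#'
#' @param cfg a `sim_config` (uses `markers`, `divergence`, `breeds`).
#' @return Named list of per-breed frequency vectors; attribute
#'   `ancestral`.
#' @export
simulate_founder_frequencies <- function(cfg) {
  m <- cfg$markers
  p0 <- stats::runif(m, 0.1, 0.9)
  out <- lapply(cfg$breeds, function(b) {
    pmin(pmax(p0 + stats::rnorm(m, 0, sqrt(cfg$divergence * p0 * (1 - p0))), 0.02), 0.98)
  })
  names(out) <- cfg$breeds
  attr(out, "ancestral") <- p0
  out
}

#' Simulate a multi-breed discrete-generation pedigree
#'
#' Random mating within breed: each generation's offspring draw a sire from
#' a limited sire team and a dam from the previous generation's females.
#' Birth dates spread over the generation's year block and the configured
#' intake months; no cross-breed matings.
#'
#' @param cfg a `sim_config`.
#' @return A sorted `pedigree`.
#' @export
simulate_pedigree <- function(cfg) {
  rows <- list()
  for (b in cfg$breeds) {
    nf <- cfg$founders_per_breed
    ids <- sprintf("%s_G0_%04d", b, seq_len(nf))
    sex <- rep(c("M", "F"), length.out = nf)
    rows[[length(rows) + 1L]] <- data.frame(
      animal = ids, sire = "0", dam = "0",
      birth_year = cfg$start_year + sample(0:(cfg$year_gap - 1L), nf, replace = TRUE),
      birth_month = sample(cfg$birth_months, nf, replace = TRUE),
      breed = b, sex = sex, stringsAsFactors = FALSE)
    prev <- data.frame(animal = ids, sex = sex, stringsAsFactors = FALSE)
    for (g in seq_len(cfg$generations - 1L)) {
      no <- cfg$offspring_per_gen
      males <- prev$animal[prev$sex == "M"]
      females <- prev$animal[prev$sex == "F"]
      sire_team <- sample(males, min(cfg$n_sires, length(males)))
      ids <- sprintf("%s_G%d_%04d", b, g, seq_len(no))
      sex <- sample(c("M", "F"), no, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = ids,
        sire = sample(sire_team, no, replace = TRUE),
        dam = sample(females, no, replace = TRUE),
        birth_year = cfg$start_year + g * cfg$year_gap +
          sample(0:(cfg$year_gap - 1L), no, replace = TRUE),
        birth_month = sample(cfg$birth_months, no, replace = TRUE),
        breed = b, sex = sex, stringsAsFactors = FALSE)
      prev <- data.frame(animal = ids, sex = sex, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  sort_pedigree(pedigree(d$animal, d$sire, d$dam, d$birth_year, d$birth_month,
                         d$breed, d$sex))
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders are drawn in Hardy-Weinberg proportions from their breed's
#' allele frequencies; every descendant receives one allele per parent per
#' locus (Mendelian transmission, loci independent).
#'
#' @param ped a sorted `pedigree`.
#' @param founder_freqs named list of per-breed frequency vectors.
#' @param m number of markers (defaults to the frequency vector length).
#' @param seed optional RNG seed.
#' @return A `genotype_matrix` over all pedigree animals.
#' @export
gene_drop_genotypes <- function(ped, founder_freqs, m = NULL, seed = NULL) {
  assert_sorted(ped)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m)) m <- length(founder_freqs[[1]])
  n <- nrow(ped)
  pi <- parent_index(ped)
  codes <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    p <- founder_freqs[[ped$breed[i]]]
    a1 <- if (s > 0L) stats::rbinom(m, 1L, codes[s, ] / 2) else stats::rbinom(m, 1L, p)
    a2 <- if (d > 0L) stats::rbinom(m, 1L, codes[d, ] / 2) else stats::rbinom(m, 1L, p)
    codes[i, ] <- a1 + a2
  }
  genotype_matrix(codes, animal_ids = ped$animal,
                  marker_ids = sprintf("M%05d", seq_len(m)),
                  breed_of = stats::setNames(ped$breed, ped$animal))
}

# effective-dimension labels: trait x breed
sim_labels <- function(cfg) {
  as.vector(outer(c("ADG", "WEI", "MUS"), cfg$breeds, paste, sep = "_"))
}

# target genetic correlation matrix over (trait, breed) dimensions;
# cross-breed blocks use the between-breed r_g times the averaged
# within-breed trait-correlation pattern, eigen-clipped to PSD
sim_target_correlation <- function(cfg) {
  nb <- length(cfg$breeds)
  Rb <- lapply(cfg$breeds, function(b) {
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- cfg$cor_adg_wei[b]
    R[1, 3] <- R[3, 1] <- cfg$cor_adg_mus[b]
    R[2, 3] <- R[3, 2] <- cfg$cor_wei_mus[b]
    R
  })
  names(Rb) <- cfg$breeds
  S <- matrix(0, 3 * nb, 3 * nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      blk <- if (i == j) Rb[[i]] else cfg$rg_between[i, j] * (Rb[[i]] + Rb[[j]]) / 2
      S[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3] <- blk
    }
  }
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 0) {
    S <- e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
    dg <- sqrt(diag(S))
    S <- S / tcrossprod(dg)
  }
  labs <- as.vector(vapply(cfg$breeds, function(b) paste(c("ADG", "WEI", "MUS"), b, sep = "_"),
                           character(3)))
  dimnames(S) <- list(labs, labs)
  # reorder to trait-major labels
  S[sim_labels(cfg), sim_labels(cfg)]
}

sim_sigma2_u <- function(cfg) {
  labs <- sim_labels(cfg)
  h2 <- c(cfg$h2_adg, cfg$h2_wei, cfg$h2_mus)
  names(h2) <- c(paste0("ADG_", cfg$breeds), paste0("WEI_", cfg$breeds),
                 paste0("MUS_", cfg$breeds))
  sdP <- c(rep(cfg$sd_adg, length(cfg$breeds)), rep(cfg$sd_wei, length(cfg$breeds)),
           rep(cfg$sd_mus, length(cfg$breeds)))
  names(sdP) <- names(h2)
  (h2 * sdP^2)[labs]
}

#' Simulate true breeding values
#'
#' Marker-effect model (default): per-marker effect vectors over all
#' (trait, breed) dimensions are drawn from a multivariate normal whose
#' correlation matches the configured within-breed trait correlations and
#' between-breed correlations, scaled so each breed's own-trait genetic
#' variance hits its `h2 x phenotypic variance` target; true breeding
#' values are the centered genotypes times the effects. The infinitesimal
#' mode draws founder values and Mendelian-sampling deviations down the
#' pedigree instead (cross-breed dimensions then carry no signal).
#'
#' @param ped a sorted `pedigree`.
#' @param genotypes a `genotype_matrix` (ignored in infinitesimal mode).
#' @param cfg a `sim_config`.
#' @param founder_freqs the per-breed founder frequencies used to scale
#'   marker-effect variances (marker mode).
#' @return An object of class `sim_truth`: `bv` (animals x trait_breed
#'   matrix), `sigma2_u`, `sigma2_e`, `G0_target`, `labels`.
#' @export
simulate_breeding_values <- function(ped, genotypes, cfg, founder_freqs = NULL) {
  labs <- sim_labels(cfg)
  s2u <- sim_sigma2_u(cfg)
  Corr <- sim_target_correlation(cfg)
  h2 <- c(stats::setNames(cfg$h2_adg, paste0("ADG_", cfg$breeds)),
          stats::setNames(cfg$h2_wei, paste0("WEI_", cfg$breeds)),
          stats::setNames(cfg$h2_mus, paste0("MUS_", cfg$breeds)))[labs]
  s2e <- s2u * (1 - h2) / h2
  if (cfg$genetic_model == "marker") {
    if (is.null(founder_freqs)) stop("marker mode needs founder frequencies")
    m <- cfg$markers
    scale_b <- vapply(cfg$breeds, function(b) {
      p <- founder_freqs[[b]]
      sum(2 * p * (1 - p))
    }, numeric(1))
    sd_alpha <- sqrt(s2u / scale_b[sub("^[A-Z]+_", "", labs)])
    L <- t(chol(Corr + diag(1e-10, length(labs))))
    E <- matrix(stats::rnorm(m * length(labs)), m, length(labs)) %*% t(L)
    E <- sweep(E, 2, sd_alpha, "*")
    W <- genotypes$codes[ped$animal, , drop = FALSE] - 1
    W[is.na(W)] <- 0
    bv <- W %*% E
  } else {
    n <- nrow(ped)
    pi <- parent_index(ped)
    f <- compute_inbreeding(ped)
    Sigma_full <- diag(sqrt(s2u)) %*% Corr %*% diag(sqrt(s2u))
    bv <- matrix(0, n, length(labs))
    # per breed, own-breed trait triplet only
    for (b in cfg$breeds) {
      cols <- match(paste(c("ADG", "WEI", "MUS"), b, sep = "_"), labs)
      Sb <- Sigma_full[cols, cols]
      Lb <- t(chol(Sb + diag(1e-12 * diag(Sb))))
      for (i in seq_len(n)) {
        if (ped$breed[i] != b) next
        s <- pi$sire[i]; d <- pi$dam[i]
        if (s == 0L && d == 0L) {
          bv[i, cols] <- as.vector(Lb %*% stats::rnorm(3))
        } else {
          pa <- if (s > 0L) bv[s, cols] else rep(0, 3)
          da <- if (d > 0L) bv[d, cols] else rep(0, 3)
          fs <- if (s > 0L) f[s] else 0
          fd <- if (d > 0L) f[d] else 0
          msc <- if (s > 0L && d > 0L) 0.5 * (1 - 0.5 * (fs + fd)) else 0.75
          bv[i, cols] <- 0.5 * (pa + da) + sqrt(msc) * as.vector(Lb %*% stats::rnorm(3))
        }
      }
    }
  }
  dimnames(bv) <- list(ped$animal, labs)
  G0 <- diag(sqrt(s2u)) %*% Corr %*% diag(sqrt(s2u))
  dimnames(G0) <- list(labs, labs)
  structure(list(bv = bv, sigma2_u = s2u, sigma2_e = s2e, G0_target = G0,
                 labels = labs), class = "sim_truth")
}

#' Own-breed true breeding values for one trait
#' @param truth a `sim_truth`.
#' @param ped the `pedigree`.
#' @param trait `"ADG"`, `"WEI"` or `"MUS"`.
#' @return Named numeric vector over all animals.
#' @export
true_bv_for <- function(truth, ped, trait = "ADG") {
  cols <- paste(trait, ped$breed, sep = "_")
  stats::setNames(truth$bv[cbind(ped$animal, cols)], ped$animal)
}

#' Simulate performance-test phenotypes
#'
#' `y = breed mean + contemporary-group effect + farm effect + covariate
#' effect + true BV + residual`, with the residual variance set from the
#' configured heritability and the target genetic variance. Phenotypes are
#' generated for the configured sex (young bulls by default) in the tested
#' cohorts (all non-founder generations); WEI carries an initial-test-
#' weight covariate and MUS an age-at-measurement covariate.
#'
#' @param truth a `sim_truth`.
#' @param ped a sorted `pedigree`.
#' @param cfg a `sim_config`.
#' @return A phenotype data frame (one row per pedigree animal; trait
#'   columns `NA` for unphenotyped animals).
#' @export
simulate_phenotypes <- function(truth, ped, cfg) {
  n <- nrow(ped)
  pi <- parent_index(ped)
  tested <- (pi$sire > 0L | pi$dam > 0L)
  phenotyped <- tested & (cfg$pheno_sex == "all" | ped$sex == cfg$pheno_sex)
  cg <- paste(ped$breed, ped$birth_year, sprintf("%02d", ped$birth_month), sep = "_")
  farm <- paste(ped$breed, sample.int(cfg$farms_per_breed, n, replace = TRUE), sep = "_F")
  init_weight <- stats::rnorm(n, 300, 30)
  age <- stats::rnorm(n, 365, 15)
  sdP <- c(ADG = cfg$sd_adg, WEI = cfg$sd_wei, MUS = cfg$sd_mus)
  means <- list(ADG = cfg$mean_adg, WEI = cfg$mean_wei, MUS = cfg$mean_mus)
  cov_effect <- list(ADG = rep(0, n), WEI = 0.8 * (init_weight - 300),
                     MUS = 0.3 * (age - 365))
  out <- data.frame(animal = ped$animal, breed = ped$breed, sex = ped$sex,
                    birth_year = ped$birth_year, birth_month = ped$birth_month,
                    cg = cg, farm = farm, init_weight = init_weight, age = age,
                    stringsAsFactors = FALSE)
  for (tr in c("ADG", "WEI", "MUS")) {
    cg_eff <- stats::setNames(stats::rnorm(length(unique(cg)), 0, cfg$cg_sd_frac * sdP[tr]),
                              unique(cg))
    farm_eff <- stats::setNames(stats::rnorm(length(unique(farm)), 0, cfg$farm_sd_frac * sdP[tr]),
                                unique(farm))
    lab <- paste(tr, ped$breed, sep = "_")
    bv <- truth$bv[cbind(ped$animal, lab)]
    s2e <- truth$sigma2_e[lab]
    y <- means[[tr]][ped$breed] + cg_eff[cg] + farm_eff[farm] + cov_effect[[tr]] +
      bv + stats::rnorm(n, 0, sqrt(s2e))
    y[!phenotyped] <- NA
    out[[tolower(tr)]] <- as.numeric(y)
  }
  out
}

#' Choose which animals are genotyped
#'
#' Genotypes the configured proportion of phenotyped males, always
#' including the most recent generation first (selection candidates), plus
#' all sires with phenotyped offspring.
#'
#' @param ped a sorted `pedigree`.
#' @param pheno phenotype table.
#' @param cfg a `sim_config`.
#' @return Character vector of genotyped animal ids.
#' @export
choose_genotyped <- function(ped, pheno, cfg) {
  tcols <- intersect(c("adg", "wei", "mus"), names(pheno))
  has_ph <- pheno$animal[rowSums(!is.na(pheno[, tcols, drop = FALSE])) > 0]
  out <- character(0)
  for (b in cfg$breeds) {
    cand <- ped$animal[ped$breed == b & ped$animal %in% has_ph]
    ord <- order(-ped$birth_year[match(cand, ped$animal)])
    keep <- cand[ord][seq_len(ceiling(cfg$genotyping_prop * length(cand)))]
    out <- c(out, keep)
  }
  sires <- unique(ped$sire[ped$animal %in% has_ph])
  sires <- setdiff(sires, "0")
  sort(unique(c(out, sires)))
}

#' Simulate a complete multi-breed dataset
#'
#' Runs the whole generator: founder frequencies, pedigree, gene-dropped
#' genotypes (of the genotyped subset), true breeding values and
#' phenotypes.
#'
#' @param cfg a `sim_config`.
#' @return List of class `sim_dataset` with `ped`, `geno`, `pheno`,
#'   `truth`, `founder_freqs`, `genotyped_ids`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  freqs <- simulate_founder_frequencies(cfg)
  ped <- simulate_pedigree(cfg)
  geno_all <- if (cfg$genetic_model == "marker") {
    gene_drop_genotypes(ped, freqs, m = cfg$markers)
  } else NULL
  truth <- simulate_breeding_values(ped, geno_all, cfg, founder_freqs = freqs)
  pheno <- simulate_phenotypes(truth, ped, cfg)
  genotyped <- if (!is.null(geno_all)) choose_genotyped(ped, pheno, cfg) else character(0)
  geno <- if (!is.null(geno_all)) {
    genotype_matrix(geno_all$codes[genotyped, , drop = FALSE],
                    breed_of = geno_all$breed_of[genotyped])
  } else NULL
  structure(list(ped = ped, geno = geno, pheno = pheno, truth = truth,
                 founder_freqs = freqs, genotyped_ids = genotyped, cfg = cfg),
            class = "sim_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, genotypes in both dialects
#' (`genotypes.ped`/`.map` and `genotypes.txt`), `truth.csv` and a
#' `manifest.yaml`.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if absent).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$ped, file.path(dir, "pedigree.csv"))
  utils::write.csv(dataset$pheno, file.path(dir, "phenotypes.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$geno)) {
    write_plink(dataset$geno, file.path(dir, "genotypes"))
    write_blupf90(dataset$geno, file.path(dir, "genotypes.txt"))
  }
  tr <- data.frame(animal = rownames(dataset$truth$bv), dataset$truth$bv,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    breeds = dataset$cfg$breeds, markers = dataset$cfg$markers,
    generations = dataset$cfg$generations, seed = dataset$cfg$seed,
    n_animals = nrow(dataset$ped), n_genotyped = length(dataset$genotyped_ids),
    sigma2_u = as.list(dataset$truth$sigma2_u)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory.
#' @return List with `ped`, `pheno`, `geno` (if present), `truth_bv`.
#' @export
read_dataset <- function(dir) {
  ped <- sort_pedigree(read_pedigree(file.path(dir, "pedigree.csv")))
  pheno <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                           colClasses = c(animal = "character"))
  geno <- if (file.exists(file.path(dir, "genotypes.ped"))) {
    read_plink(file.path(dir, "genotypes"))
  } else NULL
  tr <- utils::read.csv(file.path(dir, "truth.csv"), check.names = FALSE,
                        colClasses = c(animal = "character"))
  bv <- as.matrix(tr[, -1, drop = FALSE])
  rownames(bv) <- tr$animal
  list(ped = ped, pheno = pheno, geno = geno, truth_bv = bv)
}
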