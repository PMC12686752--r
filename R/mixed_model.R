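#' Variance components container
#'
#' @param G0 symmetric genetic (co)variance matrix over the effective
#'   traits (traits, or traits-within-breeds in the correlated multi-breed
#'   model).
#' @param R0 positive residual variances per effective trait (residuals are
#'   uncorrelated within and across effective traits).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(G0, R0) {
  G0 <- as.matrix(G0)
  if (nrow(G0) != ncol(G0) || max(abs(G0 - t(G0))) > 1e-8 * max(abs(G0), 1e-300)) {
    stop("G0 must be symmetric")
  }
  ev <- eigen((G0 + t(G0)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) stop("G0 must be positive semi-definite")
  R0 <- as.numeric(R0)
  if (length(R0) != nrow(G0)) stop("R0 length must match G0 dimension")
  if (any(R0 <= 0)) stop("residual variances must be positive")
  structure(list(G0 = G0, R0 = R0), class = "variance_components")
}

# model specification: which traits, how breeds enter, which K
#' Model specification for an evaluation
#'
#' @param traits `"ADG"` or `c("ADG", "WEI", "MUS")`.
#' @param breed_handling `"separate"` (caller runs one breed at a time),
#'   `"pooled"` (breeds share one trait), or `"correlated_traits"` (the
#'   trait is modelled as a different, correlated trait per breed).
#' @param relationship `"pedigree"` or `"single_step"`.
#' @param G_variant `"vanraden1"`, `"breedwise"` or `"metafounder"`.
#' @param name scenario label.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(traits = "ADG",
                       breed_handling = c("pooled", "separate", "correlated_traits"),
                       relationship = c("pedigree", "single_step"),
                       G_variant = c("vanraden1", "breedwise", "metafounder"),
                       name = "custom") {
  breed_handling <- match.arg(breed_handling)
  relationship <- match.arg(relationship)
  G_variant <- match.arg(G_variant)
  if (breed_handling == "correlated_traits" && !identical(traits, "ADG")) {
    stop("the correlated-traits multi-breed model is defined for ADG only")
  }
  structure(list(name = name, traits = traits, breed_handling = breed_handling,
                 relationship = relationship, G_variant = G_variant),
            class = "model_spec")
}

#' Read a model specification from YAML
#' @param path YAML file with fields `traits`, `breed_handling`,
#'   `relationship`, `G_variant`, `name`.
#' @return A `model_spec`.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  model_spec(traits = unlist(y$traits), breed_handling = y$breed_handling,
             relationship = y$relationship, G_variant = y$G_variant,
             name = if (is.null(y$name)) "custom" else y$name)
}

trait_column <- function(trait) c(ADG = "adg", WEI = "wei", MUS = "mus")[[trait]]
trait_covariate <- function(trait) switch(trait, WEI = "init_weight", MUS = "age", NULL)

# farm levels to drop for estimability: one per connected component of the
# record-level CG-farm bipartite graph (drop-first generalized to nested
# designs, e.g. farms nested in breeds under pooled multi-breed models)
farm_levels_dropped <- function(cg, farm) {
  lv_cg <- unique(cg)
  lv_f <- unique(farm)
  parent <- seq_len(length(lv_cg) + length(lv_f))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ci <- match(cg, lv_cg)
  fi <- length(lv_cg) + match(farm, lv_f)
  for (r in seq_along(ci)) {
    a <- find(ci[r]); b <- find(fi[r])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(length(lv_cg) + seq_along(lv_f), find, integer(1))
  lv_f[!duplicated(comp)]
}

indicator_matrix <- function(x, levels, prefix) {
  M <- Matrix::sparseMatrix(i = seq_along(x), j = match(x, levels), x = 1,
                            dims = c(length(x), length(levels)))
  colnames(M) <- paste0(prefix, levels)
  M
}

# design matrix for one effective trait: CG factor (all levels), farm
# factor (one level dropped per estimability group), optional covariate
fixed_design <- function(d, covariate = NULL) {
  cg <- as.character(d$cg)
  X <- indicator_matrix(cg, unique(cg), "cg:")
  farm <- as.character(d$farm)
  lv_farm <- unique(farm)
  if (length(lv_farm) > 1L) {
    drop <- farm_levels_dropped(cg, farm)
    keep <- setdiff(lv_farm, drop)
    if (length(keep)) {
      Xf <- indicator_matrix(farm, lv_farm, "farm:")[, match(keep, lv_farm), drop = FALSE]
      X <- cbind(X, Xf)
    }
  }
  if (!is.null(covariate)) {
    cv <- Matrix::Matrix(d[[covariate]] - mean(d[[covariate]]), ncol = 1, sparse = TRUE)
    colnames(cv) <- covariate
    X <- cbind(X, cv)
  }
  X
}

#' Build incidence structures for an evaluation
#'
#' Produces, per effective trait, the response vector, the fixed-effect
#' design (contemporary group as a full factor, farm of origin with its
#' first level dropped, and the trait's covariate: initial test weight for
#' WEI, age at measurement for MUS) and the animal incidence matrix.
#' Records with a missing value for a trait are excluded from that trait's
#' rows; contemporary groups left empty are dropped with the factor level.
#'
#' @param pheno phenotype data frame with columns `animal`, `breed`, `cg`,
#'   `farm`, `adg`, `wei`, `mus`, `init_weight`, `age`.
#' @param spec a [model_spec()].
#' @param animal_ids ordered ids of the genetic-effect levels (the rows of
#'   the relationship matrix the evaluation will use; may include
#'   metafounder ids, which simply receive no records).
#' @return A list of class `mme_blocks`: per effective trait `y`, `X`, `Z`,
#'   record animal ids; plus the effective trait names and `animal_ids`.
#' @export
build_incidence <- function(pheno, spec, animal_ids) {
  animal_ids <- as.character(animal_ids)
  stopifnot(inherits(spec, "model_spec"))
  if (!all(pheno$animal %in% animal_ids)) {
    stop("phenotyped animal(s) missing from the relationship matrix ids")
  }
  eff <- effective_traits(spec, pheno)
  blocks <- lapply(eff$defs, function(def) {
    d <- pheno
    if (!is.null(def$breed)) d <- d[d$breed == def$breed, , drop = FALSE]
    yv <- d[[trait_column(def$trait)]]
    d <- d[!is.na(yv), , drop = FALSE]
    if (nrow(d) == 0L) stop("no records for effective trait ", def$label)
    y <- d[[trait_column(def$trait)]]
    X <- fixed_design(d, trait_covariate(def$trait))
    Z <- Matrix::sparseMatrix(i = seq_len(nrow(d)), j = match(d$animal, animal_ids),
                              x = 1, dims = c(nrow(d), length(animal_ids)))
    list(label = def$label, y = y, X = X, Z = Z, animal = d$animal)
  })
  structure(list(blocks = blocks, traits = eff$labels, animal_ids = animal_ids),
            class = "mme_blocks")
}

# effective-trait definitions for a model spec
effective_traits <- function(spec, pheno) {
  if (spec$breed_handling == "correlated_traits") {
    breeds <- sort(unique(pheno$breed))
    defs <- lapply(breeds, function(b) list(trait = "ADG", breed = b,
                                            label = paste0("ADG_", b)))
    list(defs = defs, labels = vapply(defs, `[[`, character(1), "label"))
  } else {
    defs <- lapply(spec$traits, function(tr) list(trait = tr, breed = NULL, label = tr))
    list(defs = defs, labels = spec$traits)
  }
}

#' Assemble Henderson's mixed-model equations
#'
#' Multivariate animal model with genetic covariance `G0 (x) K` and
#' diagonal residual covariance: the coefficient matrix is
#' `[[X'R^-1X, X'R^-1Z], [Z'R^-1X, Z'R^-1Z + G0^-1 (x) K^-1]]` with
#' solutions ordered fixed effects (by trait) first, then animal effects
#' stacked by trait.
#'
#' @param blocks an `mme_blocks` from [build_incidence()].
#' @param K_inverse sparse inverse relationship matrix over
#'   `blocks$animal_ids`.
#' @param vc a [variance_components()] conformable with the effective
#'   traits.
#' @return A list of class `mme` with `LHS`, `RHS` and layout metadata.
#' @export
assemble_mme <- function(blocks, K_inverse, vc) {
  Tn <- length(blocks$blocks)
  if (nrow(vc$G0) != Tn) stop("variance components dimension (", nrow(vc$G0),
                              ") does not match effective traits (", Tn, ")")
  na <- length(blocks$animal_ids)
  if (!all(dim(K_inverse) == c(na, na))) stop("K_inverse dimension mismatch")
  r <- vc$R0
  Xs <- lapply(blocks$blocks, `[[`, "X")
  Zs <- lapply(blocks$blocks, `[[`, "Z")
  ys <- lapply(blocks$blocks, `[[`, "y")
  XtX <- Matrix::bdiag(lapply(seq_len(Tn), function(t) Matrix::crossprod(Xs[[t]]) / r[t]))
  XtZ <- Matrix::bdiag(lapply(seq_len(Tn), function(t) Matrix::crossprod(Xs[[t]], Zs[[t]]) / r[t]))
  ZtZ <- Matrix::bdiag(lapply(seq_len(Tn), function(t) Matrix::crossprod(Zs[[t]]) / r[t]))
  G0inv <- chol2inv(chol(vc$G0))
  Kron <- Matrix::kronecker(Matrix::Matrix(G0inv, sparse = TRUE), K_inverse)
  LHS <- rbind(cbind(XtX, XtZ), cbind(Matrix::t(XtZ), ZtZ + Kron))
  RHS <- c(unlist(lapply(seq_len(Tn), function(t) as.vector(Matrix::crossprod(Xs[[t]], ys[[t]])) / r[t])),
           unlist(lapply(seq_len(Tn), function(t) as.vector(Matrix::crossprod(Zs[[t]], ys[[t]])) / r[t])))
  n_fixed <- vapply(Xs, ncol, integer(1))
  structure(list(LHS = Matrix::forceSymmetric(LHS), RHS = RHS, n_fixed = n_fixed,
                 n_animals = na, n_traits = Tn, traits = blocks$traits,
                 animal_ids = blocks$animal_ids,
                 fixed_names = unlist(lapply(Xs, colnames))),
            class = "mme")
}

# Cholesky of the MME coefficient matrix, with a tiny ridge retry on the
# (possibly rank-deficient) fixed-effect block
mme_cholesky <- function(mme) {
  ch <- tryCatch(Matrix::Cholesky(mme$LHS, LDL = FALSE),
                 error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(ch)) return(list(ch = ch, LHS = mme$LHS))
  nf <- sum(mme$n_fixed)
  ridge <- Matrix::sparseMatrix(i = seq_len(nf), j = seq_len(nf),
                                x = 1e-8 * mean(Matrix::diag(mme$LHS)[seq_len(nf)]),
                                dims = dim(mme$LHS))
  warning("singular fixed-effect block; confounded levels absorbed via a small ridge")
  LHS <- Matrix::forceSymmetric(mme$LHS + ridge)
  list(ch = Matrix::Cholesky(LHS, LDL = FALSE), LHS = LHS)
}

#' Solve the mixed-model equations
#'
#' Sparse Cholesky solve of the assembled system; the relative residual
#' norm is checked against `tol`.
#'
#' @param mme an `mme` from [assemble_mme()].
#' @param tol relative residual tolerance.
#' @return A list of class `evaluation_result`: `ebv` (animals x effective
#'   traits, covering every animal in the relationship matrix), `fixed`
#'   (named solutions per trait) and `residual_norm`.
#' @export
solve_mme <- function(mme, tol = 1e-10) {
  fac <- mme_cholesky(mme)
  sol <- as.vector(Matrix::solve(fac$ch, mme$RHS, system = "A"))
  res <- as.vector(fac$LHS %*% sol - mme$RHS)
  rn <- sqrt(sum(res^2)) / max(sqrt(sum(mme$RHS^2)), 1e-300)
  if (rn > tol) stop("mixed-model solve did not reach tolerance: relative residual ", format(rn))
  nf <- sum(mme$n_fixed)
  u <- matrix(sol[nf + seq_len(mme$n_animals * mme$n_traits)],
              nrow = mme$n_animals, ncol = mme$n_traits,
              dimnames = list(mme$animal_ids, mme$traits))
  fx <- split(sol[seq_len(nf)], rep(seq_along(mme$n_fixed), mme$n_fixed))
  names(fx) <- mme$traits
  fnames <- split(mme$fixed_names, rep(seq_along(mme$n_fixed), mme$n_fixed))
  for (t in seq_along(fx)) names(fx[[t]]) <- fnames[[t]]
  structure(list(ebv = u, fixed = fx, residual_norm = rn), class = "evaluation_result")
}

#' Define the rebasing base population
#'
#' The base group is, per breed, the phenotyped bulls born in the given
#' years.
#'
#' @param ped a `pedigree`.
#' @param pheno phenotype table (animals with at least one non-missing
#'   trait count as phenotyped).
#' @param years integer vector of birth years forming the base cohorts.
#' @return Named list breed -> character ids.
#' @export
define_base_group <- function(ped, pheno, years) {
  has_ph <- pheno$animal[rowSums(!is.na(pheno[, intersect(c("adg", "wei", "mus"),
                                                          names(pheno)), drop = FALSE])) > 0]
  sel <- ped$animal %in% has_ph & ped$sex == "M" & ped$birth_year %in% years
  out <- split(ped$animal[sel], ped$breed[sel])
  empty <- setdiff(unique(ped$breed), names(out))
  if (length(empty)) stop("empty base group for breed(s): ", paste(empty, collapse = ", "))
  out
}

#' Rebase EBVs to a base population
#'
#' For every breed and effective trait, the mean EBV of that breed's base
#' group is subtracted from the EBVs of that breed's animals, so the base
#' group averages zero after rebasing.
#'
#' @param result an `evaluation_result`.
#' @param ped the `pedigree` (source of each animal's breed).
#' @param base_ids named list breed -> ids (see [define_base_group()]).
#' @return The `evaluation_result` with an added `rebased` matrix.
#' @export
rebase_ebv <- function(result, ped, base_ids) {
  ebv <- result$ebv
  breed_of <- stats::setNames(ped$breed, ped$animal)
  reb <- ebv
  for (b in names(base_ids)) {
    ids <- intersect(base_ids[[b]], rownames(ebv))
    if (length(ids) == 0L) stop("empty base group for breed ", b)
    rows <- which(breed_of[rownames(ebv)] == b)
    if (length(rows) == 0L) next
    shift <- colMeans(ebv[ids, , drop = FALSE])
    reb[rows, ] <- sweep(ebv[rows, , drop = FALSE], 2, shift, "-")
  }
  result$rebased <- reb
  result
}

#' Rescale variance components to the metafounder base
#'
#' Genetic (co)variances estimated on the ordinary pedigree base are
#' expressed on the metafounder (Gamma) base by dividing by
#' `k = 1 + mean(diag(Gamma))/2 - mean(Gamma)`.
#'
#' @param vc a [variance_components()].
#' @param Gamma metafounder relationship matrix (or a
#'   `metafounder_assignment`).
#' @return Rescaled `variance_components`, with attribute `k`.
#' @export
scale_variances_metafounder <- function(vc, Gamma) {
  if (inherits(Gamma, "metafounder_assignment")) Gamma <- Gamma$Gamma
  k <- 1 + mean(diag(Gamma)) / 2 - mean(Gamma)
  if (k <= 0) stop("metafounder scaling factor k is not positive: ", format(k))
  out <- variance_components(vc$G0 / k, vc$R0)
  attr(out, "k") <- k
  out
}
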