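#' Construct a genotype matrix object
#'
#' Stores additive SNP codes (0/1/2 copies of the alternative allele, `NA`
#' for missing) for a set of animals, plus each animal's breed.
#'
#' @param codes integer/numeric matrix, animals x markers, entries in
#'   {0, 1, 2, NA}.
#' @param animal_ids,marker_ids identifiers; defaults taken from dimnames.
#' @param breed_of named character vector mapping animal id to breed.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, animal_ids = rownames(codes),
                            marker_ids = colnames(codes), breed_of = NULL) {
  codes <- as.matrix(codes)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(nrow(codes)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(codes)))
  ok <- is.na(codes) | codes %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(codes) <- list(animal_ids, marker_ids)
  if (is.null(breed_of)) {
    breed_of <- stats::setNames(rep("B1", nrow(codes)), animal_ids)
  }
  if (!all(animal_ids %in% names(breed_of))) stop("breed_of must cover all animal ids")
  structure(list(codes = codes, animal_ids = animal_ids, marker_ids = marker_ids,
                 breed_of = breed_of[animal_ids]), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Genotype quality control
#'
#' Applies, in a fixed order and a single pass: SNP call rate, animal call
#' rate, minor allele frequency, and Mendelian conflicts against genotyped
#' parents (opposite homozygotes). Thresholds follow common practice for
#' medium-density bovine chips: SNPs with call rate < 0.95, animals with
#' call rate < 0.95, SNPs with MAF < 0.05 (MAF exactly at the threshold is
#' retained), and SNPs whose parent-offspring conflict rate exceeds
#' `mendel_rate` (default: any conflict) are removed.
#'
#' @param g a `genotype_matrix`.
#' @param ped a sorted `pedigree` (used to find genotyped parent-offspring
#'   pairs); `NULL` skips the Mendelian step.
#' @param snp_cr,an_cr,maf,mendel_rate thresholds in `[0, 1]`.
#' @return A list with the filtered `genotype_matrix` and a `qc_report`
#'   (removal lists per cause with the offending statistic).
#' @export
qc_genotypes <- function(g, ped = NULL, snp_cr = 0.95, an_cr = 0.95,
                         maf = 0.05, mendel_rate = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (th in c(snp_cr, an_cr, maf, mendel_rate)) {
    if (th < 0 || th > 1) stop("QC thresholds must lie in [0, 1]")
  }
  codes <- g$codes
  rep_list <- list()

  snp_call <- 1 - colMeans(is.na(codes))
  drop_snp <- snp_call < snp_cr
  rep_list$removed_snps_callrate <- data.frame(
    id = colnames(codes)[drop_snp], statistic = snp_call[drop_snp],
    row.names = NULL, stringsAsFactors = FALSE)
  codes <- codes[, !drop_snp, drop = FALSE]

  an_call <- 1 - rowMeans(is.na(codes))
  drop_an <- an_call < an_cr
  rep_list$removed_animals_callrate <- data.frame(
    id = rownames(codes)[drop_an], statistic = an_call[drop_an],
    row.names = NULL, stringsAsFactors = FALSE)
  codes <- codes[!drop_an, , drop = FALSE]
  if (nrow(codes) == 0L || ncol(codes) == 0L) stop("no genotypes left after call-rate QC")

  p <- colMeans(codes, na.rm = TRUE) / 2
  mafv <- pmin(p, 1 - p)
  drop_maf <- mafv < maf
  rep_list$removed_snps_maf <- data.frame(
    id = colnames(codes)[drop_maf], statistic = mafv[drop_maf],
    row.names = NULL, stringsAsFactors = FALSE)
  codes <- codes[, !drop_maf, drop = FALSE]

  if (!is.null(ped)) {
    conf <- mendel_conflict_rate(codes, ped)
    drop_men <- !is.na(conf) & conf > mendel_rate
    rep_list$removed_snps_mendel <- data.frame(
      id = colnames(codes)[drop_men], statistic = conf[drop_men],
      row.names = NULL, stringsAsFactors = FALSE)
    codes <- codes[, !drop_men, drop = FALSE]
  } else {
    rep_list$removed_snps_mendel <- data.frame(id = character(), statistic = numeric(),
                                               stringsAsFactors = FALSE)
  }
  if (nrow(codes) == 0L || ncol(codes) == 0L) stop("no genotypes left after QC")

  out <- genotype_matrix(codes, breed_of = g$breed_of[rownames(codes)])
  report <- structure(c(rep_list, list(thresholds = list(
    snp_cr = snp_cr, an_cr = an_cr, maf = maf, mendel_rate = mendel_rate))),
    class = "qc_report")
  list(genotypes = out, report = report)
}

# per-SNP rate of opposite-homozygote conflicts over genotyped
# parent-offspring pairs (NA where no informative pair exists)
mendel_conflict_rate <- function(codes, ped) {
  ids <- rownames(codes)
  off <- ped$animal %in% ids
  pairs <- rbind(
    data.frame(o = ped$animal[off], p = ped$sire[off], stringsAsFactors = FALSE),
    data.frame(o = ped$animal[off], p = ped$dam[off], stringsAsFactors = FALSE)
  )
  pairs <- pairs[pairs$p %in% ids, , drop = FALSE]
  m <- ncol(codes)
  if (nrow(pairs) == 0L) return(rep(NA_real_, m))
  go <- codes[pairs$o, , drop = FALSE]
  gp <- codes[pairs$p, , drop = FALSE]
  informative <- !is.na(go) & !is.na(gp)
  conflict <- informative & ((go == 0 & gp == 2) | (go == 2 & gp == 0))
  n_inf <- colSums(informative)
  rate <- ifelse(n_inf > 0, colSums(conflict) / n_inf, NA_real_)
  rate
}

#' Serialize a QC report to CSV
#' @param report a `qc_report` from [qc_genotypes()].
#' @param path output CSV path.
#' @export
write_qc_report <- function(report, path) {
  causes <- c("removed_snps_callrate", "removed_animals_callrate",
              "removed_snps_maf", "removed_snps_mendel")
  rows <- do.call(rbind, lapply(causes, function(cz) {
    d <- report[[cz]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(id = d$id, cause = cz, statistic = d$statistic, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(id = character(), cause = character(),
                                        statistic = numeric(), stringsAsFactors = FALSE)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
}

#' Allele frequencies
#'
#' Frequency of the counted (alternative) allele per marker, over
#' non-missing calls, either pooled (`grouping = "all"`) or within breed.
#'
#' @param g a `genotype_matrix`.
#' @param grouping `"all"` for pooled frequencies or `"by_breed"` for a
#'   per-breed list.
#' @return Numeric vector (pooled) or named list of vectors (per breed).
#' @export
allele_frequencies <- function(g, grouping = c("all", "by_breed")) {
  grouping <- match.arg(grouping)
  freq1 <- function(codes, label) {
    nn <- colSums(!is.na(codes))
    if (any(nn == 0L)) {
      stop("marker(s) with no non-missing call in group ", label, ": ",
           paste(utils::head(colnames(codes)[nn == 0L], 3), collapse = ", "))
    }
    colMeans(codes, na.rm = TRUE) / 2
  }
  if (grouping == "all") return(freq1(g$codes, "all"))
  breeds <- unique(g$breed_of)
  out <- lapply(breeds, function(b) freq1(g$codes[g$breed_of == b, , drop = FALSE], b))
  names(out) <- breeds
  out
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = M M' / sum_m 2 p_m (1 - p_m)` with `M` the genotype codes centered
#' by `2 p_m`; missing codes are mean-imputed (`2 p_m`, i.e. contribute 0).
#'
#' @param g a `genotype_matrix` (post QC).
#' @param p allele frequencies per marker, strictly inside (0, 1); defaults
#'   to observed frequencies.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
build_G_vanraden1 <- function(g, p = allele_frequencies(g, "all")) {
  codes <- g$codes
  if (length(p) != ncol(codes)) stop("frequency vector length must match marker count")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must lie strictly in (0, 1); run MAF QC first")
  M <- sweep(codes, 2, 2 * p, "-")
  M[is.na(M)] <- 0
  denom <- sum(2 * p * (1 - p))
  G <- tcrossprod(M) / denom
  (G + t(G)) / 2
}

#' Breed-wise scaled genomic relationship matrix
#'
#' Centers and scales genotypes by breed-specific allele frequencies: the
#' entry for animals i (breed b) and j (breed b') is
#' `sum_m (x_im - 2 p_bm)(x_jm - 2 p_b'm) / sqrt(s_b s_b')` with
#' `s_b = sum_m 2 p_bm (1 - p_bm)`. Within-breed blocks therefore equal
#' VanRaden G built on that breed with its own frequencies.
#'
#' @param g a `genotype_matrix` with breeds assigned.
#' @param p_by_breed named list of per-breed frequency vectors (defaults to
#'   observed per-breed frequencies).
#' @return Dense symmetric matrix.
#' @export
build_G_breedwise <- function(g, p_by_breed = allele_frequencies(g, "by_breed")) {
  codes <- g$codes
  breeds <- unique(g$breed_of)
  if (!all(breeds %in% names(p_by_breed))) stop("every breed needs a frequency vector")
  n <- nrow(codes)
  Mc <- matrix(0, n, ncol(codes), dimnames = dimnames(codes))
  scl <- numeric(n)
  for (b in breeds) {
    rows <- which(g$breed_of == b)
    p <- p_by_breed[[b]]
    # markers monomorphic within a breed contribute 0 to its centered codes
    # and to its scaling sum; only an all-monomorphic breed is an error
    sb <- sum(2 * p * (1 - p))
    if (sb <= 0) stop("breed ", b, ": no polymorphic marker; cannot scale")
    Mb <- sweep(codes[rows, , drop = FALSE], 2, 2 * p, "-")
    Mb[is.na(Mb)] <- 0
    Mc[rows, ] <- Mb
    scl[rows] <- sb
  }
  G <- tcrossprod(Mc) / sqrt(tcrossprod(scl))
  (G + t(G)) / 2
}

#' Genomic relationship matrix on the 0.5-frequency base
#'
#' `G05 = Z Z' / (m / 2)` with `Z` the codes minus 1 (missing set to 0).
#' This base makes G compatible with the metafounder pedigree matrix
#' A(Gamma).
#'
#' @param g a `genotype_matrix` (post QC).
#' @return Dense symmetric matrix.
#' @export
build_G_05 <- function(g) {
  Z <- g$codes - 1
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / (ncol(Z) / 2)
  (G + t(G)) / 2
}

#' Estimate the metafounder Gamma matrix from breed allele frequencies
#'
#' Moment estimator: `gamma_b = 8 Var_m(p_bm)` and
#' `gamma_bb' = 8 Cov_m(p_bm, p_b'm)`, with population (1/m) moments across
#' markers. The result is clipped to positive semi-definite by zeroing
#' negative eigenvalues.
#'
#' @param p_by_breed named list of per-breed frequency vectors over a common
#'   marker set (at least 2 markers).
#' @return A [metafounder_assignment()] holding the breeds and Gamma.
#' @export
estimate_gamma <- function(p_by_breed) {
  P <- do.call(cbind, p_by_breed)
  if (nrow(P) < 2L) stop("at least 2 markers are required to estimate Gamma")
  m <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P), "-")
  Gamma <- 8 * crossprod(Pc) / m
  e <- eigen((Gamma + t(Gamma)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Gamma <- e$vectors %*% (ev * t(e$vectors))
  Gamma <- (Gamma + t(Gamma)) / 2
  dimnames(Gamma) <- list(names(p_by_breed), names(p_by_breed))
  metafounder_assignment(names(p_by_breed), Gamma)
}

#' Blend a genomic with a pedigree relationship matrix
#'
#' `w G + (1 - w) A22`, the standard guard making the genomic block
#' positive definite (default `w = 0.95`).
#'
#' @param G,A22 conformable symmetric matrices over the same animals in the
#'   same order (checked via dimnames when present).
#' @param w blending weight in `[0, 1]`.
#' @return Dense symmetric matrix.
#' @export
blend_G <- function(G, A22, w = 0.95) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 must be conformable")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22))) {
    stop("G and A22 animal orders differ")
  }
  w * G + (1 - w) * A22
}

#' Single-step combined relationship matrix inverse
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G_b^-1 - A22^-1]]` on the genotyped block,
#' where `G_b` is the blended genomic matrix.
#'
#' @param A_inv sparse inverse pedigree relationship matrix (possibly the
#'   metafounder-augmented one).
#' @param A22 pedigree relationships among genotyped animals.
#' @param G_blended blended genomic relationship matrix (same order as
#'   `A22`).
#' @param genotyped_index integer positions of the genotyped animals within
#'   the rows of `A_inv`.
#' @return Sparse symmetric `dgCMatrix`.
#' @export
build_H_inverse <- function(A_inv, A22, G_blended, genotyped_index) {
  n <- nrow(A_inv)
  ng <- length(genotyped_index)
  if (ng == 0L) return(A_inv)
  if (!all(dim(G_blended) == c(ng, ng)) || !all(dim(A22) == c(ng, ng))) {
    stop("A22/G_blended dimensions must match the genotyped index")
  }
  chG <- tryCatch(chol(G_blended), error = function(e) NULL)
  if (is.null(chG)) stop("blended G is not positive definite; increase the A22 blending weight")
  Ginv <- chol2inv(chG)
  A22inv <- chol2inv(chol(A22))
  corr <- Ginv - A22inv
  corr <- (corr + t(corr)) / 2
  Corr <- Matrix::sparseMatrix(
    i = rep(genotyped_index, times = ng),
    j = rep(genotyped_index, each = ng),
    x = as.vector(corr), dims = c(n, n))
  Matrix::forceSymmetric(A_inv + Corr)
}
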