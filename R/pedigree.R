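#' Construct a pedigree object
#'
#' A pedigree is a data frame with one row per animal carrying its parents,
#' birth date (year and month), breed and sex. Unknown parents are coded
#' `"0"`. All relationship-matrix builders in the package require the
#' pedigree to be topologically sorted (parents before offspring); use
#' [sort_pedigree()] first.
#'
#' @param animal,sire,dam character vectors of animal and parent identifiers;
#'   `"0"` (or `NA`) marks an unknown parent.
#' @param birth_year,birth_month integer birth date components.
#' @param breed character breed labels.
#' @param sex character sex labels (`"M"`/`"F"`).
#' @return An object of class `pedigree` (a data frame).
#' @export
pedigree <- function(animal, sire, dam, birth_year, birth_month, breed, sex) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)] <- "0"
  if (anyDuplicated(animal)) {
    stop("duplicated animal ids: ", paste(unique(animal[duplicated(animal)])[1:3], collapse = ", "))
  }
  ped <- data.frame(
    animal = animal, sire = sire, dam = dam,
    birth_year = as.integer(birth_year), birth_month = as.integer(birth_month),
    breed = as.character(breed), sex = as.character(sex),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(c(sire, dam), c("0", animal))
  if (length(bad)) stop("parent id(s) absent from pedigree: ", paste(bad[1:min(3, length(bad))], collapse = ", "))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree from CSV
#'
#' Expects a header `animal,sire,dam,birth_year,birth_month,breed,sex`
#' with `"0"` for unknown parents.
#'
#' @param path path to the CSV file.
#' @return A `pedigree` object (unsorted; run [sort_pedigree()]).
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, colClasses = c(
    animal = "character", sire = "character", dam = "character"
  ))
  pedigree(d$animal, d$sire, d$dam, d$birth_year, d$birth_month, d$breed, d$sex)
}

#' Write a pedigree to CSV
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
}

# integer parent indices (0 = unknown) into the pedigree row order
parent_index <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  si[ped$sire == "0"] <- 0L
  di[ped$dam == "0"] <- 0L
  si[is.na(si)] <- -1L
  di[is.na(di)] <- -1L
  if (any(si < 0L) || any(di < 0L)) {
    bad <- c(ped$sire[si < 0L], ped$dam[di < 0L])
    stop("parent id(s) absent from pedigree: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  list(sire = si, dam = di)
}

#' Topologically sort a pedigree
#'
#' Orders records so every parent precedes its offspring; within that
#' constraint the order is stable by birth date (year, month) then id.
#' Fails with an informative error on pedigree loops (an animal that is its
#' own ancestor).
#'
#' @param ped a `pedigree`.
#' @return The sorted `pedigree`, with attribute `sorted = TRUE`.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  pi <- parent_index(ped)
  # generation depth: founders 0, otherwise 1 + max(parent depth)
  depth <- rep.int(0L, n)
  repeat {
    ds <- ifelse(pi$sire > 0L, depth[pmax(pi$sire, 1L)], -1L)
    dd <- ifelse(pi$dam > 0L, depth[pmax(pi$dam, 1L)], -1L)
    new <- pmax(ds, dd) + 1L
    if (identical(new, depth)) break
    depth <- new
    if (max(depth) > n) {
      # a cycle inflates depth without bound; locate one member
      cyc <- which(depth > n)[1L]
      stop("pedigree loop detected involving animal ", ped$animal[cyc])
    }
  }
  ord <- order(depth, ped$birth_year, ped$birth_month, ped$animal)
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

assert_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) {
    pi <- parent_index(ped)
    i <- seq_len(nrow(ped))
    if (any(pi$sire >= i) || any(pi$dam >= i)) {
      stop("pedigree is not sorted (parents must precede offspring); call sort_pedigree() first")
    }
  }
  invisible(ped)
}

# Mendelian-sampling variance of each animal given parent inbreeding
mendelian_variance <- function(si, di, f) {
  both <- si > 0L & di > 0L
  one_s <- si > 0L & di == 0L
  one_d <- di > 0L & si == 0L
  m <- rep.int(1, length(si))
  m[both] <- 0.5 - 0.25 * (f[si[both]] + f[di[both]])
  m[one_s] <- 0.75 - 0.25 * f[si[one_s]]
  m[one_d] <- 0.75 - 0.25 * f[di[one_d]]
  m
}

#' Pedigree inbreeding coefficients
#'
#' Recursive (Meuwissen-Luo style) computation of Wright's inbreeding
#' coefficient F for every animal: for each animal the generalized Cholesky
#' row over its ancestors is accumulated, giving
#' `1 + F = sum_j L_j^2 d_j` with `d_j` the ancestor's Mendelian-sampling
#' variance. Animals with any unknown parent get F = 0.
#'
#' @param ped a sorted `pedigree`.
#' @return Numeric vector of F, one per animal, in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  assert_sorted(ped)
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire; di <- pi$dam
  f <- numeric(n)
  dvec <- numeric(n) # Mendelian-sampling variance, filled as we go
  L <- numeric(n)
  for (i in seq_len(n)) {
    dvec[i] <- mendelian_variance(si[i], di[i], f)[1L]
    if (si[i] == 0L || di[i] == 0L) {
      f[i] <- 0
      next
    }
    # accumulate L over ancestors of i (including i), descending index order
    touched <- i
    L[i] <- 1
    acc <- 0
    ptr <- i
    # process indices from i down; maintain explicit membership via L != 0
    todo <- i
    while (length(todo)) {
      j <- todo[1L]
      todo <- todo[-1L]
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * dvec[j]
      for (p in c(si[j], di[j])) {
        if (p > 0L) {
          if (L[p] == 0) {
            todo <- c(todo, p)
            touched <- c(touched, p)
          }
          L[p] <- L[p] + 0.5 * lj
        }
      }
      L[j] <- 0 # consumed
      todo <- todo[order(-todo)]
    }
    L[touched] <- 0
    f[i] <- acc - 1
  }
  names(f) <- ped$animal
  f
}

#' Numerator relationship matrix A
#'
#' Dense tabular construction: `a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)})` and
#' `a_ii = 1 + 0.5 a_{s(i),d(i)}`.
#'
#' @param ped a sorted `pedigree`.
#' @return A symmetric dense matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  assert_sorted(ped)
  n <- nrow(ped)
  pi <- parent_index(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha_i k k'` with `alpha_i = 1/m_i`, `m_i` its Mendelian-sampling
#' variance given parental F, and `k` carrying 1 at the animal and -0.5 at
#' each known parent.
#'
#' @param ped a sorted `pedigree`.
#' @param f inbreeding coefficients from [compute_inbreeding()]; computed
#'   if missing.
#' @return A sparse symmetric `dgCMatrix` with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped, f = NULL) {
  assert_sorted(ped)
  if (is.null(f)) f <- compute_inbreeding(ped)
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire; di <- pi$dam
  alpha <- 1 / mendelian_variance(si, di, f)
  ii <- seq_len(n)
  # triplets: (i,i), (i,s), (s,i), (i,d), (d,i), (s,s), (d,d), (s,d), (d,s)
  ri <- ii; ci <- ii; xi <- alpha
  hs <- si > 0L; hd <- di > 0L
  add <- function(r, c, x) {
    ri <<- c(ri, r); ci <<- c(ci, c); xi <<- c(xi, x)
  }
  add(ii[hs], si[hs], -0.5 * alpha[hs]); add(si[hs], ii[hs], -0.5 * alpha[hs])
  add(ii[hd], di[hd], -0.5 * alpha[hd]); add(di[hd], ii[hd], -0.5 * alpha[hd])
  add(si[hs], si[hs], 0.25 * alpha[hs])
  add(di[hd], di[hd], 0.25 * alpha[hd])
  hb <- hs & hd
  add(si[hb], di[hb], 0.25 * alpha[hb]); add(di[hb], si[hb], 0.25 * alpha[hb])
  Ainv <- Matrix::sparseMatrix(i = ri, j = ci, x = xi, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationships among genotyped animals (A22)
#'
#' Principal submatrix of A on the genotyped animals, in the order of
#' `genotyped_ids`. When a dense A is supplied it is indexed directly;
#' when a pedigree is supplied, the submatrix is obtained without forming
#' A, by solving `A^-1 X = E` for the genotyped unit columns (Colleau's
#' indirect method).
#'
#' @param A_or_ped a dense A with dimnames, or a sorted `pedigree`.
#' @param genotyped_ids character ids, a subset of the pedigree ids.
#' @return Dense symmetric matrix in `genotyped_ids` order.
#' @export
extract_A22 <- function(A_or_ped, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (inherits(A_or_ped, "pedigree")) {
    ped <- A_or_ped
    idx <- match(genotyped_ids, ped$animal)
    if (anyNA(idx)) stop("unknown genotyped id(s): ",
                         paste(utils::head(genotyped_ids[is.na(idx)], 3), collapse = ", "))
    Ainv <- build_A_inverse(ped)
    ch <- Matrix::Cholesky(Ainv, LDL = FALSE)
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(nrow(ped), length(idx)))
    X <- Matrix::solve(ch, E, system = "A")
    A22 <- as.matrix(X[idx, , drop = FALSE])
  } else {
    A <- A_or_ped
    idx <- match(genotyped_ids, rownames(A))
    if (anyNA(idx)) stop("unknown genotyped id(s): ",
                         paste(utils::head(genotyped_ids[is.na(idx)], 3), collapse = ", "))
    A22 <- A[idx, idx, drop = FALSE]
  }
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(genotyped_ids, genotyped_ids)
  A22
}

#' Metafounder assignment
#'
#' Maps each breed to a metafounder and stores the metafounder
#' (co)variance matrix Gamma: `gamma_b` on the diagonal (self-relationship
#' of breed b's metafounder) and `gamma_bb'` across breeds.
#'
#' @param breeds character vector of breed labels (one metafounder each).
#' @param Gamma symmetric numeric matrix, `length(breeds)` square.
#' @return An object of class `metafounder_assignment`.
#' @export
metafounder_assignment <- function(breeds, Gamma) {
  breeds <- as.character(breeds)
  Gamma <- as.matrix(Gamma)
  if (!isTRUE(all.equal(Gamma, t(Gamma), tolerance = 1e-10))) stop("Gamma must be symmetric")
  if (nrow(Gamma) != length(breeds)) stop("Gamma dimension must match number of breeds")
  if (any(diag(Gamma) < 0) || any(diag(Gamma) > 2)) stop("diagonal of Gamma must lie in [0, 2]")
  ev <- eigen((Gamma + t(Gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("Gamma must be positive semi-definite")
  dimnames(Gamma) <- list(breeds, breeds)
  structure(list(breeds = breeds, Gamma = Gamma), class = "metafounder_assignment")
}

# augment a sorted pedigree with one metafounder per breed; unknown parents
# of breed-b animals become breed b's metafounder. Returns parent indices
# into the augmented order (metafounders first) plus bookkeeping.
augment_with_metafounders <- function(ped, mf) {
  assert_sorted(ped)
  nb <- length(mf$breeds)
  miss <- setdiff(unique(ped$breed), mf$breeds)
  if (length(miss)) stop("breed(s) without a metafounder: ", paste(miss, collapse = ", "))
  pi <- parent_index(ped)
  mfi <- match(ped$breed, mf$breeds) # metafounder index 1..nb per animal
  si <- ifelse(pi$sire > 0L, pi$sire + nb, mfi)
  di <- ifelse(pi$dam > 0L, pi$dam + nb, mfi)
  list(nb = nb, sire = as.integer(si), dam = as.integer(di), mf_of = mfi)
}

#' Metafounder numerator relationship matrix A(Gamma)
#'
#' Tabular recursion on the pedigree augmented with one metafounder per
#' breed: the metafounder block is initialized to Gamma, every unknown
#' parent of a breed-b animal is replaced by breed b's metafounder, and the
#' usual recursion runs over animals. With Gamma = 0 the result equals the
#' ordinary A.
#'
#' @param ped a sorted `pedigree`.
#' @param mf a [metafounder_assignment()].
#' @param keep_metafounders return the augmented matrix including
#'   metafounder rows/columns (default drops them).
#' @return Dense symmetric matrix; attribute `mendelian_variance` carries
#'   the per-animal Mendelian-sampling variances under Gamma.
#' @export
build_A_gamma <- function(ped, mf, keep_metafounders = FALSE) {
  aug <- augment_with_metafounders(ped, mf)
  nb <- aug$nb
  n <- nrow(ped)
  N <- nb + n
  A <- matrix(0, N, N)
  A[seq_len(nb), seq_len(nb)] <- mf$Gamma
  mvar <- numeric(n)
  for (k in seq_len(n)) {
    i <- nb + k
    s <- aug$sire[k]; d <- aug$dam[k]
    j <- seq_len(i - 1L)
    v <- 0.5 * (A[j, s] + A[j, d])
    A[j, i] <- v
    A[i, j] <- v
    A[i, i] <- 1 + 0.5 * A[s, d]
    mvar[k] <- A[i, i] - 0.25 * (A[s, s] + 2 * A[s, d] + A[d, d])
  }
  ids <- c(paste0("MF_", mf$breeds), ped$animal)
  dimnames(A) <- list(ids, ids)
  out <- if (keep_metafounders) A else A[-seq_len(nb), -seq_len(nb), drop = FALSE]
  attr(out, "mendelian_variance") <- mvar
  out
}

#' Sparse inverse of the augmented metafounder relationship matrix
#'
#' Generalized Henderson assembly on the metafounder-augmented pedigree:
#' every animal has two (possibly metafounder) parents, its contribution is
#' `k k'/m_i` with `m_i = a_ii - 0.25 (a_ss + 2 a_sd + a_dd)`, and the
#' metafounder block receives `Gamma^-1`. The inverse is of the augmented
#' matrix (metafounders first); the animal block of the corresponding
#' covariance matrix equals A(Gamma).
#'
#' @inheritParams build_A_gamma
#' @return Sparse symmetric `dgCMatrix` of dimension
#'   `n_breeds + n_animals`; attribute `n_metafounders`.
#' @export
build_A_gamma_inverse <- function(ped, mf) {
  aug <- augment_with_metafounders(ped, mf)
  nb <- aug$nb
  n <- nrow(ped)
  N <- nb + n
  AG <- build_A_gamma(ped, mf, keep_metafounders = TRUE)
  mvar <- attr(AG, "mendelian_variance")
  if (any(mvar <= 0)) stop("non-positive Mendelian-sampling variance; Gamma too extreme")
  alpha <- 1 / mvar
  ii <- nb + seq_len(n)
  si <- aug$sire; di <- aug$dam
  ri <- ii; ci <- ii; xi <- alpha
  ri <- c(ri, ii, si, ii, di, si, di, si, di)
  ci <- c(ci, si, ii, di, ii, si, di, di, si)
  xi <- c(xi, rep(-0.5 * alpha, 4), 0.25 * alpha, 0.25 * alpha, 0.25 * alpha, 0.25 * alpha)
  G_inv <- solve(mf$Gamma + diag(1e-12, nb))
  gi <- rep(seq_len(nb), each = nb)
  gj <- rep(seq_len(nb), times = nb)
  ri <- c(ri, gi); ci <- c(ci, gj); xi <- c(xi, as.vector(G_inv))
  ids <- c(paste0("MF_", mf$breeds), ped$animal)
  M <- Matrix::sparseMatrix(i = ri, j = ci, x = xi, dims = c(N, N), dimnames = list(ids, ids))
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  attr(M, "n_metafounders") <- nb
  M
}
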