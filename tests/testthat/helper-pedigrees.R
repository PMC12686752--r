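# fixtures and independent oracles shared across test files

# random overlapping-generation pedigree with possible inbreeding
random_pedigree <- function(n, n_founders = 10, seed = 1) {
  set.seed(seed)
  animal <- sprintf("A%04d", seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- rep(c("M", "F"), length.out = n)
  for (i in (n_founders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "M")
    fems <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- animal[sample(males, 1)]
    dam[i] <- animal[sample(fems, 1)]
  }
  sort_pedigree(pedigree(animal, sire, dam,
                         birth_year = 2000 + seq_len(n) %/% 20,
                         birth_month = 1 + seq_len(n) %% 12,
                         breed = "B1", sex = sex))
}

# independent oracle: numerator relationships by memoized recursive
# coancestry, phi(i,j) = 0.5 (phi(i, s_j) + phi(i, d_j)) for j younger,
# phi(i,i) = 0.5 (1 + phi(s_i, d_i)); A = 2 phi
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal); si[ped$sire == "0"] <- 0L
  di <- match(ped$dam, ped$animal); di[ped$dam == "0"] <- 0L
  phi <- matrix(NA_real_, n, n)
  get <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + get(si[i], di[i]))
    } else {
      jj <- max(i, j); ii <- min(i, j)
      0.5 * (get(ii, si[jj]) + get(ii, di[jj]))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in i:n) get(i, j)
  A <- 2 * phi
  diag(A) <- 2 * diag(phi)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# tiny named pedigree builder for hand-constructed cases
ped_from_text <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r), stringsAsFactors = FALSE)
  }))
  sort_pedigree(pedigree(d$animal, d$sire, d$dam,
                         as.integer(d$year), rep(1L, nrow(d)),
                         if (is.null(d$breed)) "B1" else d$breed,
                         if (is.null(d$sex)) "M" else d$sex))
}
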