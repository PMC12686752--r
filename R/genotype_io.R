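#' Write genotypes as a PLINK text .ped/.map pair
#'
#' Codes are written as biallelic calls `A A` / `A B` / `B B` (`0 0` for
#' missing), so code = number of B alleles. The .map file carries dummy
#' positions (one chromosome, marker order preserved).
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`).
#' @export
write_plink <- function(g, prefix) {
  codes <- g$codes
  al <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  lines <- vapply(seq_len(nrow(codes)), function(i) {
    x <- codes[i, ]
    calls <- ifelse(is.na(x), "0 0", al[as.character(x)])
    paste(g$breed_of[i], g$animal_ids[i], "0", "0", "0", "-9",
          paste(calls, collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  map <- paste("1", g$marker_ids, "0", seq_along(g$marker_ids))
  writeLines(map, paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read genotypes from a PLINK text .ped/.map pair
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return A `genotype_matrix`; the .ped family id column is used as breed.
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), colClasses = "character")
  marker_ids <- map[[2]]
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(trimws(lines), "[ \t]+")
  m <- length(marker_ids)
  codes <- matrix(NA_real_, length(parts), m)
  ids <- character(length(parts))
  breeds <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 6 + 2 * m) stop("malformed .ped line ", i)
    breeds[i] <- p[1]
    ids[i] <- p[2]
    a1 <- p[seq(7, length(p), by = 2)]
    a2 <- p[seq(8, length(p), by = 2)]
    miss <- a1 == "0" | a2 == "0"
    codes[i, ] <- (a1 == "B") + (a2 == "B")
    codes[i, miss] <- NA
  }
  genotype_matrix(codes, animal_ids = ids, marker_ids = marker_ids,
                  breed_of = stats::setNames(breeds, ids))
}

#' Write genotypes in the fixed-width single-column dialect
#'
#' One line per animal: the id, whitespace, then a contiguous string of
#' 0/1/2 codes with 5 for missing (the dialect used by common BLUP software
#' for SNP files).
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @export
write_blupf90 <- function(g, path) {
  codes <- g$codes
  codes[is.na(codes)] <- 5
  lines <- paste(g$animal_ids, apply(codes, 1, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from the fixed-width single-column dialect
#'
#' @param path input file path.
#' @param breed_of optional named breed map; defaults to a single breed.
#' @param marker_ids optional marker names.
#' @return A `genotype_matrix`.
#' @export
read_blupf90 <- function(path, breed_of = NULL, marker_ids = NULL) {
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(parts, `[`, character(1), 1L)
  gstr <- vapply(parts, `[`, character(1), 2L)
  m <- unique(nchar(gstr))
  if (length(m) != 1L) stop("inconsistent genotype string lengths")
  codes <- matrix(as.numeric(unlist(strsplit(gstr, ""))), nrow = length(ids),
                  ncol = m, byrow = TRUE)
  codes[codes == 5] <- NA
  genotype_matrix(codes, animal_ids = ids, marker_ids = marker_ids, breed_of = breed_of)
}
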