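#' Diploid multilocus genotype dataset
#'
#' Container for codominant diploid genotypes of individuals assigned to study
#' cells with planar coordinates. Allele calls are stored as two integer
#' matrices (`a1`, `a2`, individuals x loci) holding positive integer allele
#' codes; a missing genotype is `NA` in both matrices. The pair is unordered:
#' the constructor normalises each call so that `a1 <= a2`.
#'
#' @param individuals character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes;
#'   `NA` marks a missing call. Codes must be positive integers (0 is never a
#'   valid in-memory code; it is a file-format convention only).
#' @param cell character vector, study-cell label per individual.
#' @param coords numeric matrix (individuals x 2) of planar x/y in metres.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(individuals, loci, a1, a2, cell,
                             coords = NULL) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  n <- length(individuals)
  L <- length(loci)
  if (anyDuplicated(individuals)) stop("duplicate individual identifiers")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  a1 <- matrix(as.integer(a1), n, L)
  a2 <- matrix(as.integer(a2), n, L)
  if (!identical(dim(a1), dim(a2))) stop("a1/a2 dimension mismatch")
  if (nrow(a1) != n || ncol(a1) != L) stop("call matrices must be individuals x loci")
  bad <- xor(is.na(a1), is.na(a2))
  if (any(bad)) stop("half-missing calls: both alleles must be present or both NA")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers")
  # unordered pair: store sorted
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  cell <- as.character(cell)
  if (length(cell) != n) stop("one cell label per individual required")
  if (anyNA(cell)) stop("missing cell labels")
  if (is.null(coords)) coords <- matrix(NA_real_, n, 2)
  coords <- matrix(as.numeric(coords), n, 2)
  if (any(!is.finite(coords)) && !all(is.na(coords)))
    if (any(is.infinite(coords))) stop("coordinates must be finite")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  rownames(coords) <- individuals
  colnames(coords) <- c("x", "y")
  structure(list(individuals = individuals, loci = loci,
                 a1 = a1, a2 = a2, cell = cell, coords = coords),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d cells\n",
              length(x$individuals), length(x$loci),
              length(unique(x$cell))))
  mr <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * mr))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  tab <- table(object$cell)
  cat(sprintf("genotype_dataset: %d individuals, %d loci\n",
              length(object$individuals), length(object$loci)))
  cat("individuals per cell:\n")
  print(tab)
  k <- vapply(seq_along(object$loci), function(l)
    length(unique(stats::na.omit(c(object$a1[, l], object$a2[, l])))), 0L)
  cat("alleles per locus:\n")
  print(stats::setNames(k, object$loci))
  invisible(object)
}

#' Number of distinct alleles per locus
#' @param d a `genotype_dataset`
#' @return named integer vector over loci.
#' @export
n_alleles <- function(d) {
  vapply(seq_along(d$loci), function(l)
    length(unique(stats::na.omit(c(d$a1[, l], d$a2[, l])))), 0L) |>
    stats::setNames(d$loci)
}

#' Subset a genotype dataset by individuals
#' @param d a `genotype_dataset`
#' @param keep logical/integer/character index over individuals.
#' @return a `genotype_dataset`
#' @export
subset_individuals <- function(d, keep) {
  if (is.character(keep)) keep <- match(keep, d$individuals)
  genotype_dataset(d$individuals[keep], d$loci,
                   d$a1[keep, , drop = FALSE], d$a2[keep, , drop = FALSE],
                   d$cell[keep], d$coords[keep, , drop = FALSE])
}

#' Allele count and heterozygosity summaries per cell and locus
#'
#' Internal workhorse: for one locus, returns per-cell allele dosage counts,
#' per-cell per-allele heterozygote-carrier counts and complete-genotype
#' sample sizes. Used by every frequency-based estimator.
#'
#' @param d a `genotype_dataset`
#' @param locus locus index or name
#' @param cells optional subset of cell labels (default: all, sorted)
#' @return list with `counts` (cells x alleles dosage counts), `hets`
#'   (cells x alleles count of heterozygous carriers), `n` (complete
#'   genotypes per cell), `alleles` (sorted allele codes).
#' @keywords internal
locus_counts <- function(d, locus, cells = NULL) {
  if (is.character(locus)) locus <- match(locus, d$loci)
  if (is.null(cells)) cells <- sort(unique(d$cell))
  a1 <- d$a1[, locus]; a2 <- d$a2[, locus]
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  k <- length(alleles)
  counts <- matrix(0L, length(cells), k, dimnames = list(cells, alleles))
  hets <- matrix(0L, length(cells), k, dimnames = list(cells, alleles))
  nvec <- integer(length(cells)); names(nvec) <- cells
  for (ci in seq_along(cells)) {
    sel <- ok & d$cell == cells[ci]
    nvec[ci] <- sum(sel)
    if (!nvec[ci]) next
    x1 <- match(a1[sel], alleles); x2 <- match(a2[sel], alleles)
    counts[ci, ] <- tabulate(x1, k) + tabulate(x2, k)
    h <- x1 != x2
    if (any(h)) hets[ci, ] <- tabulate(x1[h], k) + tabulate(x2[h], k)
  }
  list(counts = counts, hets = hets, n = nvec, alleles = alleles)
}

#' Per-individual allele dosage matrices for every locus
#'
#' Precomputes, for each locus, an individuals x alleles dosage matrix (0/1/2,
#' NA rows for missing calls) plus the matching heterozygote-carrier indicator
#' matrix. These make bootstrap resampling of frequency-based statistics a
#' `rowsum()` away.
#'
#' @param d a `genotype_dataset`
#' @return list over loci; each element has `dos`, `het` (matrices), `alleles`.
#' @keywords internal
dosage_tables <- function(d) {
  lapply(seq_along(d$loci), function(l) {
    a1 <- d$a1[, l]; a2 <- d$a2[, l]
    ok <- !is.na(a1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    k <- length(alleles)
    n <- length(a1)
    dos <- matrix(0, n, k, dimnames = list(d$individuals, alleles))
    het <- matrix(0, n, k, dimnames = list(d$individuals, alleles))
    x1 <- match(a1, alleles); x2 <- match(a2, alleles)
    idx <- which(ok)
    hom <- idx[x1[idx] == x2[idx]]
    hz <- idx[x1[idx] != x2[idx]]
    dos[cbind(hom, x1[hom])] <- 2
    dos[cbind(hz, x1[hz])] <- 1
    dos[cbind(hz, x2[hz])] <- 1
    het[cbind(hz, x1[hz])] <- 1
    het[cbind(hz, x2[hz])] <- 1
    dos[!ok, ] <- NA
    het[!ok, ] <- NA
    list(dos = dos, het = het, alleles = alleles)
  }) |> stats::setNames(d$loci)
}
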