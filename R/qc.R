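#' Missing-genotype rate
#'
#' Fraction of missing calls, either over the whole dataset (total missing /
#' total calls) or per individual (fraction of that row's loci missing).
#'
#' @param d a [genotype_dataset()].
#' @param scope `"dataset"` or `"individual"`.
#' @return single fraction, or named vector over individuals.
#' @export
missing_rate <- function(d, scope = c("dataset", "individual")) {
  scope <- match.arg(scope)
  if (!length(d$individuals) || !length(d$loci)) stop("empty dataset")
  miss <- is.na(d$a1)
  if (scope == "dataset") return(mean(miss))
  stats::setNames(rowMeans(miss), d$individuals)
}

#' Drop individuals exceeding a missingness threshold
#'
#' Retains exactly the individuals whose missing-call fraction is strictly
#' below `max_missing` (an individual missing exactly 30% of loci is dropped
#' at `max_missing = 0.3`). Order is preserved; the operation is idempotent.
#'
#' @param d a [genotype_dataset()].
#' @param max_missing threshold in \[0, 1\]; default 0.3.
#' @return filtered `genotype_dataset` (possibly with zero individuals).
#' @export
filter_individuals <- function(d, max_missing = 0.3) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  mr <- rowMeans(is.na(d$a1))
  keep <- which(mr < max_missing)
  subset_individuals(d, keep)
}

# Levene log-probability of a genotype table given its allele counts:
# log P = log n! + h log 2 + sum_a log c_a! - log (2n)! - sum_g log n_g!
# Computed from the multiset of genotype pairs; smaller P = less probable
# table. The test statistic is -log P.
.hwe_neglogp <- function(g1, g2) {
  n <- length(g1)
  h <- sum(g1 != g2)
  alleles <- sort(unique(c(g1, g2)))
  ca <- tabulate(match(c(g1, g2), alleles), length(alleles))
  key <- paste(pmin(g1, g2), pmax(g1, g2))
  ng <- table(key)
  logp <- lfactorial(n) + h * log(2) + sum(lfactorial(ca)) -
    lfactorial(2 * n) - sum(lfactorial(ng))
  -logp
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Guo-Thompson-style conditional exact test for one locus in one study cell.
#' All alleles observed in the cell at the locus are pooled and re-paired at
#' random `n_perm` times; the test statistic is the negative log conditional
#' (Levene) probability of the genotype table given the allele counts, and
#' the p-value is `(1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param d a [genotype_dataset()].
#' @param cell study-cell label.
#' @param locus locus name or index.
#' @param n_perm number of Monte-Carlo shuffles (>= 100).
#' @param seed integer seed (local RNG, does not disturb the global stream).
#' @return list with `p`, `statistic`, `n` (complete genotypes) and
#'   `monomorphic` flag (monomorphic locus returns p = 1).
#' @export
hwe_exact_test <- function(d, cell, locus, n_perm = 2000, seed = 1) {
  stopifnot(n_perm >= 100)
  if (is.character(locus)) locus <- match(locus, d$loci)
  sel <- d$cell == cell & !is.na(d$a1[, locus])
  g1 <- d$a1[sel, locus]; g2 <- d$a2[sel, locus]
  n <- length(g1)
  if (n < 2) stop("need >= 2 complete genotypes in cell '", cell, "'")
  if (length(unique(c(g1, g2))) < 2) {
    return(list(p = 1, statistic = 0, n = n, monomorphic = TRUE))
  }
  obs <- .hwe_neglogp(g1, g2)
  pool <- c(g1, g2)
  cnt <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample(pool)
      .hwe_neglogp(perm[seq_len(n)], perm[n + seq_len(n)]) >= obs - 1e-12
    }, logical(1)))
  })
  list(p = (1 + cnt) / (n_perm + 1), statistic = obs, n = n,
       monomorphic = FALSE)
}

#' Benjamini-Yekutieli false-discovery-rate decisions
#'
#' Step-up procedure with the `c(m) = sum(1/i)` correction valid under
#' arbitrary dependence. Returns per-test reject/accept decisions and the
#' effective raw-p cutoff (the largest ordered p satisfying the step-up
#' bound; 0 when nothing is rejected).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha target FDR level (the reference analysis used 0.013).
#' @return list with `reject` (logical, input order), `cutoff`, `adjusted`
#'   (BY-adjusted p-values).
#' @export
fdr_threshold <- function(pvalues, alpha = 0.013) {
  if (!length(pvalues)) stop("empty p-value list")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "BY")
  reject <- adj <= alpha
  m <- length(pvalues)
  cm <- sum(1 / seq_len(m))
  ord <- sort(pvalues)
  bound <- seq_len(m) * alpha / (m * cm)
  k <- which(ord <= bound)
  cutoff <- if (length(k)) ord[max(k)] else 0
  list(reject = reject, cutoff = cutoff, adjusted = adj)
}

#' Brookfield (1996) null-allele frequency estimate
#'
#' Estimator 1: `r = (He - Ho) / (1 + He)` with unbiased expected
#' heterozygosity, clipped below at zero. Appropriate when missing genotypes
#' are not assumed to be null homozygotes.
#'
#' @param d a [genotype_dataset()].
#' @param cell study-cell label.
#' @param locus locus name or index.
#' @return list with `estimate` and `monomorphic` flag (monomorphic locus
#'   returns 0 with the flag set).
#' @export
null_allele_freq <- function(d, cell, locus) {
  h <- heterozygosities(d, cell, locus)
  if (h$He == 0)
    return(list(estimate = 0, monomorphic = TRUE))
  list(estimate = max(0, (h$He - h$Ho) / (1 + h$He)), monomorphic = FALSE)
}

#' Hardy-Weinberg screening report over all cells and loci
#'
#' Runs [hwe_exact_test()] for every cell x locus combination with enough
#' data, applies the Benjamini-Yekutieli FDR correction across all tests, and
#' flags loci that are rejected in at least `drop_if_rejected_in` of the
#' cells where they were testable (default: all of them - the "consistently
#' deviates in every cell" rule).
#'
#' @param d a [genotype_dataset()].
#' @param alpha FDR level (default 0.013).
#' @param n_perm Monte-Carlo shuffles per test.
#' @param drop_if_rejected_in fraction of testable cells, default 1 (all).
#' @param seed integer seed.
#' @return list: `p` (cell x locus matrix of raw p), `reject` (same shape,
#'   post-FDR), `drop` (named logical over loci), `cutoff`. Linkage
#'   equilibrium is not tested; the report marks it `le = "not computed"`.
#' @export
hwe_screen <- function(d, alpha = 0.013, n_perm = 2000,
                       drop_if_rejected_in = 1, seed = 1) {
  cells <- sort(unique(d$cell))
  P <- matrix(NA_real_, length(cells), length(d$loci),
              dimnames = list(cells, d$loci))
  for (ci in seq_along(cells)) for (l in seq_along(d$loci)) {
    sel <- d$cell == cells[ci] & !is.na(d$a1[, l])
    if (sum(sel) < 2) next
    P[ci, l] <- hwe_exact_test(d, cells[ci], l, n_perm = n_perm,
                               seed = seed + 1000L * ci + l)$p
  }
  ok <- !is.na(P)
  fdr <- fdr_threshold(P[ok], alpha)
  R <- matrix(NA, nrow(P), ncol(P), dimnames = dimnames(P))
  R[ok] <- fdr$reject
  frac <- colSums(R, na.rm = TRUE) / pmax(1, colSums(!is.na(R)))
  testable <- colSums(!is.na(R)) > 0
  drop <- testable & frac >= drop_if_rejected_in & frac > 0
  list(p = P, reject = R, drop = drop, cutoff = fdr$cutoff,
       le = "not computed")
}
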