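#' Observed and unbiased expected heterozygosity
#'
#' For one locus in one study cell: `Ho` is the fraction of complete
#' genotypes that are heterozygous; `He` is Nei's unbiased expected
#' heterozygosity `(2n/(2n-1)) * (1 - sum p_i^2)` with `n` the number of
#' complete genotypes.
#'
#' @param d a [genotype_dataset()].
#' @param cell study-cell label.
#' @param locus locus name or index.
#' @return list with `Ho`, `He`, `n`.
#' @export
heterozygosities <- function(d, cell, locus) {
  if (is.character(locus)) locus <- match(locus, d$loci)
  sel <- d$cell == cell & !is.na(d$a1[, locus])
  n <- sum(sel)
  if (!n) stop("no complete genotypes for cell '", cell, "'")
  g1 <- d$a1[sel, locus]; g2 <- d$a2[sel, locus]
  Ho <- mean(g1 != g2)
  p <- tabulate(match(c(g1, g2), unique(c(g1, g2)))) / (2 * n)
  He <- if (length(p) < 2) 0 else (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  list(Ho = Ho, He = He, n = n)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a hypergeometric subsample of `g`
#' genes: `sum_a [1 - choose(2n - c_a, g) / choose(2n, g)]` with `c_a` the
#' observed count of allele `a` and `2n` the genes sampled in the cell.
#'
#' @param d a [genotype_dataset()].
#' @param cell study-cell label.
#' @param locus locus name or index.
#' @param g rarefaction gene count (>= 2, <= 2n).
#' @return expected allele count at depth `g`.
#' @export
allelic_richness <- function(d, cell, locus, g) {
  if (g < 2) stop("rarefaction depth g must be >= 2")
  if (is.character(locus)) locus <- match(locus, d$loci)
  sel <- d$cell == cell & !is.na(d$a1[, locus])
  if (!sum(sel)) stop("no complete genotypes for cell '", cell, "'")
  ca <- tabulate(match(c(d$a1[sel, locus], d$a2[sel, locus]),
                       unique(c(d$a1[sel, locus], d$a2[sel, locus]))))
  N <- sum(ca)
  if (g > N) stop("g exceeds sampled genes (", N, ")")
  # lchoose handles choose(N - c_a, g) = 0 when c_a > N - g
  sum(1 - exp(lchoose(N - ca, g) - lchoose(N, g)))
}

# Weir-Cockerham within-population variance components for one population at
# one locus, per allele: b2 (between individuals within pop) and c2 (within
# individuals). f = 1 - sum(c2) / sum(b2 + c2).
.wc_single_components <- function(counts, hets, n) {
  p <- counts / (2 * n)
  h <- hets / n
  c2 <- h / 2
  b2 <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cbind(b = b2, c = c2)
}

#' Multilocus Weir-Cockerham inbreeding coefficient for a study cell
#'
#' `f` estimated as a ratio of summed variance components over all loci and
#' alleles (within-individual component vs total within-population
#' component), with a percentile bootstrap-over-loci confidence interval.
#'
#' @param d a [genotype_dataset()].
#' @param cell study-cell label.
#' @param n_perm number of bootstrap resamples of loci for the CI.
#' @param seed integer seed.
#' @return list with `fis`, `ci` (length-2), `single_locus` flag (CI is
#'   undefined and returned as `NA` when only one informative locus exists).
#' @export
fis <- function(d, cell, n_perm = 10000, seed = 1) {
  if (sum(d$cell == cell) < 2) stop("need >= 2 individuals in cell")
  comp <- lapply(seq_along(d$loci), function(l) {
    lc <- locus_counts(d, l, cells = cell)
    n <- lc$n[1]
    if (n < 2 || length(lc$alleles) < 2) return(c(b = 0, c = 0))
    colSums(.wc_single_components(lc$counts[1, ], lc$hets[1, ], n))
  })
  B <- vapply(comp, `[[`, 0, "b")
  C <- vapply(comp, `[[`, 0, "c")
  informative <- (B + C) != 0
  if (!any(informative)) stop("no polymorphic loci in cell '", cell, "'")
  est <- 1 - sum(C) / sum(B + C)
  li <- which(informative)
  if (length(li) < 2)
    return(list(fis = est, ci = c(NA_real_, NA_real_), single_locus = TRUE))
  boots <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- sample(li, length(li), replace = TRUE)
    1 - sum(C[s]) / sum(B[s] + C[s])
  }, 0))
  list(fis = est,
       ci = unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)),
       single_locus = FALSE)
}

#' Per-cell genetic diversity table
#'
#' One row per study cell: `N` (individuals), `Na` (mean observed alleles
#' per locus), `AR` (rarefied allelic richness, per-locus rarefaction depth
#' = smallest gene count over cells, averaged over loci), `Ho`, `He`
#' (means over loci), and multilocus `Fis` with bootstrap CI.
#'
#' @param d a [genotype_dataset()].
#' @param n_perm bootstrap resamples for the F_IS CI.
#' @param seed integer seed.
#' @return data.frame with columns N, Na, AR, Ho, He, Fis, Fis_low, Fis_high.
#' @export
diversity_table <- function(d, n_perm = 10000, seed = 1) {
  cells <- sort(unique(d$cell))
  L <- length(d$loci)
  # per-locus rarefaction depth: min complete gene count over cells
  gmin <- vapply(seq_len(L), function(l) {
    n <- locus_counts(d, l, cells = cells)$n
    2L * min(n)
  }, 0L)
  out <- lapply(cells, function(cl) {
    ho <- he <- ar <- na <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      sel <- d$cell == cl & !is.na(d$a1[, l])
      if (!sum(sel)) next
      h <- heterozygosities(d, cl, l)
      ho[l] <- h$Ho; he[l] <- h$He
      na[l] <- length(unique(c(d$a1[sel, l], d$a2[sel, l])))
      if (gmin[l] >= 2) ar[l] <- allelic_richness(d, cl, l, gmin[l])
    }
    fv <- fis(d, cl, n_perm = n_perm, seed = child_seed(seed, cl))
    data.frame(cell = cl, N = sum(d$cell == cl),
               Na = mean(na, na.rm = TRUE), AR = mean(ar, na.rm = TRUE),
               Ho = mean(ho, na.rm = TRUE), He = mean(he, na.rm = TRUE),
               Fis = fv$fis, Fis_low = fv$ci[1], Fis_high = fv$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
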