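# Pairwise differentiation: Weir-Cockerham theta and Jost's D, with
# permutation p-values (individuals shuffled between the two cells) and
# percentile bootstrap-over-loci confidence intervals.

# Weir-Cockerham (1984) variance components for two populations at one locus,
# vectorized over alleles. counts = allele dosage counts (length k), hets =
# counts of heterozygous carriers per allele, n = complete genotypes.
# Returns sum over alleles of a (among-population) and a+b+c (total).
.wc_pair_components <- function(c1, h1, n1, c2, h2, n2) {
  if (n1 < 2 || n2 < 2) return(c(a = NA_real_, abc = NA_real_))
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  p1 <- c1 / (2 * n1); p2 <- c2 / (2 * n2)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (h1 / n1 * n1 + h2 / n2 * n2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), abc = sum(a + b + cc))
}

# Jost's D components for two populations at one locus (Nei-Chesser unbiased
# heterozygosities, two-population estimator). Returns num = Ht_est - Hs_est
# and den = 1 - Hs_est; per-locus D = 2 * num / den.
.jost_pair_components <- function(c1, n1, c2, n2) {
  if (n1 < 1 || n2 < 1) return(c(num = NA_real_, den = NA_real_))
  p1 <- c1 / (2 * n1); p2 <- c2 / (2 * n2)
  ntilde <- 2 / (1 / n1 + 1 / n2)
  hs_raw <- 1 - (sum(p1^2) + sum(p2^2)) / 2
  hs <- (2 * ntilde / (2 * ntilde - 1)) * hs_raw
  pbar <- (p1 + p2) / 2
  ht <- 1 - sum(pbar^2) + hs / (4 * ntilde)
  c(num = ht - hs, den = 1 - hs)
}

#' Jost's D from known allele frequencies (infinite-sample form)
#'
#' Exact formula path for population allele-frequency vectors:
#' `D = (r/(r-1)) * (Ht - Hs) / (1 - Hs)` with `Hs` the mean within-population
#' gene diversity and `Ht` the pooled gene diversity.
#'
#' @param p matrix (populations x alleles) of allele frequencies, rows
#'   summing to one.
#' @return Jost's D in \[0, 1\].
#' @export
jost_d_freq <- function(p) {
  p <- as.matrix(p)
  r <- nrow(p)
  stopifnot(r >= 2, all(abs(rowSums(p) - 1) < 1e-8))
  hs <- mean(1 - rowSums(p^2))
  ht <- 1 - sum(colMeans(p)^2)
  if (hs == 1) return(0)
  (r / (r - 1)) * (ht - hs) / (1 - hs)
}

# Per-locus, per-pair component table for a dataset: rows = loci, one entry
# per cell pair. Shared by estimates, permutations and bootstrap.
.pair_components <- function(d, cells, measure = c("fst", "jost")) {
  measure <- match.arg(measure)
  np <- length(cells) * (length(cells) - 1) / 2
  pr <- which(upper.tri(diag(length(cells))), arr.ind = TRUE)
  A <- B <- matrix(NA_real_, length(d$loci), np)
  for (l in seq_along(d$loci)) {
    lc <- locus_counts(d, l, cells = cells)
    for (k in seq_len(np)) {
      i <- pr[k, 1]; j <- pr[k, 2]
      v <- if (measure == "fst")
        .wc_pair_components(lc$counts[i, ], lc$hets[i, ], lc$n[i],
                            lc$counts[j, ], lc$hets[j, ], lc$n[j])
      else
        .jost_pair_components(lc$counts[i, ], lc$n[i],
                              lc$counts[j, ], lc$n[j])
      A[l, k] <- v[1]; B[l, k] <- v[2]
    }
  }
  list(A = A, B = B, pairs = pr)
}

.ratio_of_sums <- function(A, B, jost) {
  num <- colSums(A, na.rm = TRUE)
  den <- colSums(B, na.rm = TRUE)
  est <- ifelse(den == 0, 0, num / den)
  if (jost) est <- 2 * est
  est
}

.assemble <- function(v, cells, pr, clip01 = FALSE) {
  m <- matrix(0, length(cells), length(cells), dimnames = list(cells, cells))
  m[cbind(pr[, 1], pr[, 2])] <- v
  m[cbind(pr[, 2], pr[, 1])] <- v
  if (clip01) m <- pmin(m, 1)
  m
}

.pairwise_diff <- function(d, measure, n_perm, n_boot, seed) {
  cells0 <- sort(unique(d$cell))
  sizes <- table(d$cell)[cells0]
  small <- cells0[sizes < 2]
  if (length(small)) {
    warning("cells with <2 individuals excluded: ",
            paste(small, collapse = ", "))
    d <- subset_individuals(d, !(d$cell %in% small))
  }
  cells <- sort(unique(d$cell))
  if (length(cells) < 2) stop("need >= 2 cells with >= 2 individuals")
  jost <- measure == "jost"
  pc <- .pair_components(d, cells, measure)
  est <- .ratio_of_sums(pc$A, pc$B, jost)
  np <- length(est)
  L <- nrow(pc$A)
  pmat <- cilo <- cihi <- NULL
  if (n_boot > 0 && L >= 2) {
    qs <- with_seed(child_seed(seed, paste0(measure, "_boot")), {
      bs <- vapply(seq_len(n_boot), function(b) {
        s <- sample(L, L, replace = TRUE)
        .ratio_of_sums(pc$A[s, , drop = FALSE], pc$B[s, , drop = FALSE], jost)
      }, numeric(np))
      if (np == 1) dim(bs) <- c(1, n_boot)
      apply(bs, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    })
    cilo <- .assemble(qs[1, ], cells, pc$pairs)
    cihi <- .assemble(qs[2, ], cells, pc$pairs)
    if (jost) { cilo[] <- pmax(cilo, 0); cihi[] <- pmax(cihi, 0) }
  }
  if (n_perm > 0) {
    dt <- dosage_tables(d)
    pv <- numeric(np)
    for (k in seq_len(np)) {
      ci <- cells[pc$pairs[k, 1]]; cj <- cells[pc$pairs[k, 2]]
      rows <- which(d$cell %in% c(ci, cj))
      n1 <- sum(d$cell == ci)
      obs <- est[k]
      stat <- function(r1, r2) {
        num <- den <- 0
        for (l in seq_along(dt)) {
          tb <- dt[[l]]
          ok1 <- r1[!is.na(tb$dos[r1, 1])]
          ok2 <- r2[!is.na(tb$dos[r2, 1])]
          v <- if (!jost)
            .wc_pair_components(
              colSums(tb$dos[ok1, , drop = FALSE]),
              colSums(tb$het[ok1, , drop = FALSE]), length(ok1),
              colSums(tb$dos[ok2, , drop = FALSE]),
              colSums(tb$het[ok2, , drop = FALSE]), length(ok2))
          else
            .jost_pair_components(
              colSums(tb$dos[ok1, , drop = FALSE]), length(ok1),
              colSums(tb$dos[ok2, , drop = FALSE]), length(ok2))
          if (!is.na(v[1])) { num <- num + v[1]; den <- den + v[2] }
        }
        r <- if (den == 0) 0 else num / den
        if (jost) 2 * r else r
      }
      perm <- with_seed(child_seed(seed, paste0(measure, "_perm_", k)),
        vapply(seq_len(n_perm), function(b) {
          sh <- sample(rows)
          stat(sh[seq_len(n1)], sh[-seq_len(n1)])
        }, 0))
      pv[k] <- perm_p(obs, perm)
    }
    pmat <- .assemble(pv, cells, pc$pairs)
    diag(pmat) <- NA
  }
  structure(list(est = .assemble(est, cells, pc$pairs),
                 p = pmat, ci_low = cilo, ci_high = cihi,
                 measure = measure, cells = cells),
            class = "pairwise_diff")
}

#' Pairwise Weir-Cockerham F_ST between study cells
#'
#' Weir-Cockerham (1984) theta per cell pair, variance components summed over
#' loci and alleles. Optional permutation p-values (individuals of the two
#' cells randomly re-assigned, sizes preserved) and percentile
#' bootstrap-over-loci confidence intervals. Negative point estimates are
#' reported as computed, not clipped.
#'
#' @param d a [genotype_dataset()].
#' @param n_perm permutations per pair for p-values (0 = skip).
#' @param n_boot bootstrap resamples of loci for CIs (0 = skip).
#' @param seed integer seed.
#' @return object of class `pairwise_diff`: list with `est`, `p`, `ci_low`,
#'   `ci_high` (symmetric matrices, zero diagonal).
#' @export
pairwise_fst <- function(d, n_perm = 0, n_boot = 0, seed = 1) {
  .pairwise_diff(d, "fst", n_perm, n_boot, seed)
}

#' Pairwise Jost's D between study cells
#'
#' Two-population Jost's D per pair with Nei-Chesser unbiased gene
#' diversities; the multilocus value aggregates per-locus numerator and
#' denominator components by their arithmetic means (ratio of averages).
#' Confidence intervals are clipped at zero; point estimates are not.
#'
#' @inheritParams pairwise_fst
#' @return object of class `pairwise_diff` (see [pairwise_fst()]).
#' @export
pairwise_jost_d <- function(d, n_perm = 0, n_boot = 0, seed = 1) {
  .pairwise_diff(d, "jost", n_perm, n_boot, seed)
}

#' @export
print.pairwise_diff <- function(x, ...) {
  lab <- if (x$measure == "fst") "Weir-Cockerham F_ST" else "Jost's D"
  v <- ut(x$est)
  cat(sprintf("pairwise %s over %d cells: range %.4f .. %.4f (mean %.4f)\n",
              lab, length(x$cells), min(v), max(v), mean(v)))
  invisible(x)
}

#' Fast pairwise differentiation matrix from precomputed dosage tables
#'
#' Bootstrap workhorse: recomputes the full pairwise F_ST (or Jost's D)
#' matrix for an arbitrary row index into the dataset (e.g. individuals
#' resampled with replacement within cells), without re-deriving allele
#' tables.
#'
#' @param dt result of [dosage_tables()].
#' @param cellf character/factor of cell labels, one per dataset row.
#' @param idx integer rows to use (default all).
#' @param measure `"fst"` or `"jost"`.
#' @return symmetric matrix over sorted cell labels.
#' @keywords internal
diff_matrix_from_tables <- function(dt, cellf, idx = seq_along(cellf),
                                    measure = c("fst", "jost")) {
  measure <- match.arg(measure)
  jost <- measure == "jost"
  cells <- sort(unique(as.character(cellf)))
  cf <- factor(as.character(cellf)[idx], levels = cells)
  nc <- length(cells)
  pr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  num <- den <- numeric(nrow(pr))
  for (l in seq_along(dt)) {
    tb <- dt[[l]]
    dos <- tb$dos[idx, , drop = FALSE]
    het <- tb$het[idx, , drop = FALSE]
    ok <- !is.na(dos[, 1])
    counts <- rowsum(dos[ok, , drop = FALSE], cf[ok], reorder = TRUE)
    hets <- rowsum(het[ok, , drop = FALSE], cf[ok], reorder = TRUE)
    nvec <- tabulate(cf[ok], nc)
    have <- sort(unique(as.integer(cf[ok])))
    full_counts <- matrix(0, nc, ncol(dos))
    full_hets <- matrix(0, nc, ncol(dos))
    full_counts[have, ] <- counts
    full_hets[have, ] <- hets
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      v <- if (!jost)
        .wc_pair_components(full_counts[i, ], full_hets[i, ], nvec[i],
                            full_counts[j, ], full_hets[j, ], nvec[j])
      else
        .jost_pair_components(full_counts[i, ], nvec[i],
                              full_counts[j, ], nvec[j])
      if (!is.na(v[1])) { num[k] <- num[k] + v[1]; den[k] <- den[k] + v[2] }
    }
  }
  est <- ifelse(den == 0, 0, num / den)
  if (jost) est <- 2 * est
  .assemble(est, cells, pr)
}
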