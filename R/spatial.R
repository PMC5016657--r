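#' Labeled symmetric distance matrix
#'
#' Light wrapper validating the lingua-franca object of the pipeline: a
#' symmetric real matrix with zero diagonal and a kind tag.
#'
#' @param m square numeric matrix with dimnames.
#' @param kind one of `"genetic"`, `"geographic"`, `"resistance"`,
#'   `"indicator"`.
#' @return the matrix with attributes `kind`, class `dist_matrix`.
#' @export
dist_matrix <- function(m, kind = c("genetic", "geographic", "resistance",
                                    "indicator")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- seq_len(nrow(m))
  if (max(abs(m - t(m))[is.finite(m) & is.finite(t(m))]) > 1e-12)
    stop("matrix not symmetric")
  if (any(abs(diag(m)) > 0)) stop("diagonal must be zero")
  attr(m, "kind") <- kind
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Pairwise Euclidean distances between labeled points
#'
#' @param points matrix/data.frame with two columns (x, y in metres) and row
#'   labels (or a `label` column plus `x`, `y`).
#' @return a `dist_matrix` of kind `"geographic"`.
#' @export
geographic_distances <- function(points) {
  if (is.data.frame(points) && all(c("x", "y") %in% names(points))) {
    lab <- if ("cell" %in% names(points)) as.character(points$cell)
           else rownames(points)
    points <- cbind(points$x, points$y)
    rownames(points) <- lab
  }
  points <- as.matrix(points)
  if (anyDuplicated(rownames(points))) stop("duplicate labels")
  if (any(!is.finite(points))) stop("coordinates must be finite")
  m <- as.matrix(stats::dist(points))
  dist_matrix(m, "geographic")
}

#' Barrier-side indicator matrix
#'
#' Entry 1 when two cells lie on different sides of the barrier, 0 otherwise
#' (e.g. opposite banks of a major river).
#'
#' @param cells data.frame with columns `cell` and `side`.
#' @return a `dist_matrix` of kind `"indicator"`.
#' @export
barrier_indicator <- function(cells) {
  if (!"side" %in% names(cells) || anyNA(cells$side))
    stop("every cell needs a side label")
  s <- as.character(cells$side)
  m <- outer(s, s, `!=`) * 1
  dimnames(m) <- list(cells$cell, cells$cell)
  dist_matrix(m, "indicator")
}

.mantel_r <- function(a, b) stats::cor(a, b)

#' Mantel test of matrix association
#'
#' Pearson correlation of the upper-triangle entries of two conformable
#' distance matrices; significance from joint row/column permutations of the
#' second matrix, `p = (1 + #[r_perm >= r_obs]) / (n_perm + 1)` (one-tailed
#' "greater" by default, the direction isolation-by-distance predicts).
#'
#' @param A,B square symmetric matrices with matching labels/order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"greater"` or `"two.sided"`.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel <- function(A, B, n_perm = 10000, seed = 1,
                   tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)), nrow(A) >= 4)
  a <- ut(A); b <- ut(B)
  if (stats::sd(a) == 0) stop("first matrix has zero variance")
  if (stats::sd(b) == 0) stop("second matrix has zero variance")
  r <- .mantel_r(a, b)
  n <- nrow(B)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample(n)
    .mantel_r(a, ut(B[p, p]))
  }, 0))
  list(r = r, p = perm_p(r, perm, tail), n_perm = n_perm)
}

#' Partial Mantel test
#'
#' First-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` on
#' upper-triangle entries, with significance from joint row/column
#' permutations of `B`, recomputing the partial statistic each time.
#'
#' @param A,B,C conformable square symmetric matrices.
#' @inheritParams mantel
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000, seed = 1,
                           tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  stopifnot(identical(dim(A), dim(B)), identical(dim(A), dim(C)))
  a <- ut(A); b <- ut(B); cc <- ut(C)
  pr <- function(bv) {
    rab <- .mantel_r(a, bv); rac <- .mantel_r(a, cc); rbc <- .mantel_r(bv, cc)
    if (abs(rac) >= 1 - 1e-12)
      stop("degenerate conditioning: |r| between A and C is 1")
    # B fully explained by C: nothing left to correlate
    if (abs(rbc) >= 1 - 1e-12) return(0)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  r <- pr(b)
  n <- nrow(B)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample(n)
    pr(ut(B[p, p]))
  }, 0))
  list(r = r, p = perm_p(r, perm, tail), n_perm = n_perm)
}

#' Rousset's a-hat pairwise genetic distance between individuals
#'
#' Identity-probability estimator: per locus, the probability of allelic
#' identity within the two individuals of a pair (`Qw`, averaged over both)
#' is contrasted with identity between them (`Qb`, the four inter-individual
#' gene comparisons). The multilocus value is the ratio of summed components,
#' `a = sum_l (Qw_l - Qb_l) / sum_l (1 - Qw_l)`, which weights loci by their
#' within-individual diversity. May be negative; a pair with no shared typed
#' locus (or denominator zero with zero numerator) is returned as `NA` and
#' flagged for exclusion downstream.
#'
#' @param d a [genotype_dataset()].
#' @param cell optional study-cell label restricting to one cell.
#' @return a `dist_matrix` of kind `"genetic"` over individuals (entries may
#'   be `NA` when undefined).
#' @export
rousset_a <- function(d, cell = NULL) {
  if (!is.null(cell)) d <- subset_individuals(d, d$cell == cell)
  n <- length(d$individuals)
  if (n < 3) stop("need >= 3 individuals")
  L <- length(d$loci)
  m <- matrix(0, n, n, dimnames = list(d$individuals, d$individuals))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- den <- 0
    shared <- FALSE
    for (l in seq_len(L)) {
      if (is.na(d$a1[i, l]) || is.na(d$a1[j, l])) next
      shared <- TRUE
      qi <- (d$a1[i, l] == d$a2[i, l]) + (d$a1[j, l] == d$a2[j, l])
      qw <- qi / 2
      qb <- mean(outer(c(d$a1[i, l], d$a2[i, l]),
                       c(d$a1[j, l], d$a2[j, l]), `==`))
      num <- num + (qw - qb)
      den <- den + (1 - qw)
    }
    # no shared typed locus: flagged missing; fully homozygous identical
    # pair (0/0): zero distance by convention; fixed-different pair with no
    # within-individual diversity: infinite
    v <- if (!shared) NA_real_
    else if (den == 0) { if (num > 0) Inf else 0 }
    else num / den
    m[i, j] <- m[j, i] <- v
  }
  dist_matrix(m, "genetic")
}

# Smouse-Peakall squared genetic distance between individuals: half the
# squared Euclidean distance between allele-dosage vectors, summed over loci
# shared by the pair.
.sp_gsq <- function(d) {
  dt <- dosage_tables(d)
  n <- length(d$individuals)
  G <- matrix(0, n, n)
  for (l in seq_along(dt)) {
    dos <- dt[[l]]$dos
    ok <- !is.na(dos[, 1])
    dos0 <- dos; dos0[!ok, ] <- 0
    cross <- tcrossprod(dos0)
    sq <- rowSums(dos0^2)
    dd <- outer(sq, sq, `+`) - 2 * cross
    dd[!ok, ] <- 0; dd[, !ok] <- 0
    G <- G + dd / 2
  }
  dimnames(G) <- list(d$individuals, d$individuals)
  G
}

#' Multivariate spatial autocorrelogram (Smouse-Peakall)
#'
#' Squared multilocus genotype distances are double-centered into a
#' covariance matrix `C`; the autocorrelation for distance class `h` is
#' `r(h) = sum_{pairs in h} c_ij / sum_{i involved in h} c_ii`. Distance
#' classes are half-open `[lo, hi)` with the final class closed at
#' `max_dist_m`. A permutation null envelope (coordinates shuffled among
#' individuals) and a bootstrap-over-pairs CI around each `r` are attached.
#'
#' @param d a [genotype_dataset()] with coordinates.
#' @param cell optional study-cell label restricting the analysis.
#' @param class_width_m distance class width in metres (default 100).
#' @param max_dist_m upper bound in metres (default 2000).
#' @param n_perm permutations for the null envelope.
#' @param n_boot bootstrap resamples of pairs.
#' @param seed integer seed.
#' @return data.frame: `class_lo`, `class_hi`, `n_pairs`, `r`, `null_lo`,
#'   `null_hi`, `boot_lo`, `boot_hi`; attribute `degenerate` set when all
#'   individuals are genetically identical (all `r` reported 0).
#' @export
spatial_autocorrelation <- function(d, cell = NULL, class_width_m = 100,
                                    max_dist_m = 2000, n_perm = 999,
                                    n_boot = 999, seed = 1) {
  stopifnot(class_width_m > 0)
  if (!is.null(cell)) d <- subset_individuals(d, d$cell == cell)
  n <- length(d$individuals)
  if (n < 10) stop("need >= 10 individuals with coordinates")
  if (any(!is.finite(d$coords))) stop("all individuals need coordinates")
  G <- .sp_gsq(d)
  J <- diag(n) - matrix(1 / n, n, n)
  C <- -0.5 * (J %*% G %*% J)
  geo <- as.matrix(stats::dist(d$coords))
  breaks <- seq(0, max_dist_m, by = class_width_m)
  if (max(breaks) < max_dist_m) breaks <- c(breaks, max_dist_m)
  nb <- length(breaks) - 1
  pairs <- which(upper.tri(geo), arr.ind = TRUE)
  pd <- geo[pairs]
  # half-open [lo, hi); last class includes max_dist exactly
  cls <- findInterval(pd, breaks, rightmost.closed = TRUE)
  cls[pd > max_dist_m] <- NA
  degenerate <- all(abs(C) < 1e-12)
  r_of <- function(Cm) vapply(seq_len(nb), function(k) {
    sel <- which(!is.na(cls) & cls == k)
    if (length(sel) < 2) return(NA_real_)
    i <- pairs[sel, 1]; j <- pairs[sel, 2]
    denom <- sum(diag(Cm)[unique(c(i, j))])
    if (abs(denom) < 1e-300) return(0)
    sum(Cm[cbind(i, j)]) / denom
  }, 0)
  r <- if (degenerate) rep(0, nb) else r_of(C)
  perm_env <- with_seed(child_seed(seed, "ac_perm"), {
    if (degenerate) matrix(0, 2, nb)
    else {
      pm <- vapply(seq_len(n_perm), function(b) {
        p <- sample(n)
        # shuffle coordinates = relabel C rows/cols relative to geography
        Cp <- C[p, p]
        r_of(Cp)
      }, numeric(nb))
      apply(pm, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    }
  })
  boot_env <- with_seed(child_seed(seed, "ac_boot"), {
    bm <- vapply(seq_len(n_boot), function(b) {
      vapply(seq_len(nb), function(k) {
        sel <- which(!is.na(cls) & cls == k)
        if (length(sel) < 2) return(NA_real_)
        sel <- sample(sel, length(sel), replace = TRUE)
        i <- pairs[sel, 1]; j <- pairs[sel, 2]
        denom <- sum(diag(C)[unique(c(i, j))])
        if (abs(denom) < 1e-300) return(0)
        sum(C[cbind(i, j)]) / denom
      }, 0)
    }, numeric(nb))
    apply(bm, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  })
  out <- data.frame(class_lo = breaks[seq_len(nb)],
                    class_hi = breaks[-1],
                    n_pairs = vapply(seq_len(nb), function(k)
                      sum(!is.na(cls) & cls == k), 0L),
                    r = r,
                    null_lo = perm_env[1, ], null_hi = perm_env[2, ],
                    boot_lo = boot_env[1, ], boot_hi = boot_env[2, ])
  attr(out, "degenerate") <- degenerate
  out
}
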