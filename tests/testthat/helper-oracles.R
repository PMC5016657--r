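# Independent brute-force oracles, coded directly from the published
# formulas with plain loops; deliberately unshared with the package
# internals so estimator tests are dual-route.

# random small genotype dataset
random_dataset <- function(n_cells = 3, n_per_cell = 5, L = 3, k = 4,
                           miss = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_cells * n_per_cell
    a1 <- matrix(sample.int(k, n * L, TRUE), n, L)
    a2 <- matrix(sample.int(k, n * L, TRUE), n, L)
    if (miss > 0) {
      m <- matrix(runif(n * L) < miss, n, L)
      a1[m] <- NA; a2[m] <- NA
    }
    genotype_dataset(paste0("i", seq_len(n)), paste0("L", seq_len(L)),
                     a1, a2, rep(paste0("c", seq_len(n_cells)),
                                 each = n_per_cell),
                     cbind(runif(n, 0, 1000), runif(n, 0, 1000)))
  })
}

# Weir & Cockerham (1984) theta for two populations, plain transcription:
# per locus, per allele: nbar, nc, pbar, s2, hbar -> a, b, c; theta =
# sum(a) / sum(a + b + c).
wc_theta_oracle <- function(d, cell1, cell2) {
  num <- den <- 0
  for (l in seq_along(d$loci)) {
    for (pop_pair in list(c(cell1, cell2))) {
      g <- list()
      for (cc in pop_pair) {
        sel <- d$cell == cc & !is.na(d$a1[, l])
        g[[cc]] <- cbind(d$a1[sel, l], d$a2[sel, l])
      }
      alleles <- unique(c(unlist(lapply(g, as.vector))))
      if (length(alleles) < 2) next
      n1 <- nrow(g[[1]]); n2 <- nrow(g[[2]])
      if (n1 < 2 || n2 < 2) next
      r <- 2
      nbar <- (n1 + n2) / 2
      nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
      for (al in alleles) {
        p1 <- sum(g[[1]] == al) / (2 * n1)
        p2 <- sum(g[[2]] == al) / (2 * n2)
        h1 <- mean(xor(g[[1]][, 1] == al, g[[1]][, 2] == al))
        h2 <- mean(xor(g[[2]][, 1] == al, g[[2]][, 2] == al))
        pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
        s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
        hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
        a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                              (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                      (2 * nbar - 1) / (4 * nbar) * hbar)
        cc2 <- hbar / 2
        num <- num + a
        den <- den + a + b + cc2
      }
    }
  }
  num / den
}

# Weir-Cockerham single-population f, plain loops
wc_fis_oracle <- function(d, cell) {
  sc <- sb <- 0
  for (l in seq_along(d$loci)) {
    sel <- d$cell == cell & !is.na(d$a1[, l])
    g <- cbind(d$a1[sel, l], d$a2[sel, l])
    n <- nrow(g)
    alleles <- unique(as.vector(g))
    if (n < 2 || length(alleles) < 2) next
    for (al in alleles) {
      p <- sum(g == al) / (2 * n)
      h <- mean(xor(g[, 1] == al, g[, 2] == al))
      b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      cc <- h / 2
      sb <- sb + b
      sc <- sc + cc
    }
  }
  1 - sc / (sb + sc)
}

# Jost's D for two populations, Nei-Chesser unbiased heterozygosities,
# ratio-of-averages over loci, factor n/(n-1) = 2.
jost_d_oracle <- function(d, cell1, cell2) {
  nums <- dens <- numeric(0)
  for (l in seq_along(d$loci)) {
    sel1 <- d$cell == cell1 & !is.na(d$a1[, l])
    sel2 <- d$cell == cell2 & !is.na(d$a1[, l])
    n1 <- sum(sel1); n2 <- sum(sel2)
    if (n1 < 1 || n2 < 1) next
    al <- sort(unique(c(d$a1[sel1 | sel2, l], d$a2[sel1 | sel2, l])))
    p1 <- vapply(al, function(a)
      (sum(d$a1[sel1, l] == a) + sum(d$a2[sel1, l] == a)) / (2 * n1), 0)
    p2 <- vapply(al, function(a)
      (sum(d$a1[sel2, l] == a) + sum(d$a2[sel2, l] == a)) / (2 * n2), 0)
    nh <- 2 / (1 / n1 + 1 / n2)
    hs_raw <- 1 - (sum(p1^2) + sum(p2^2)) / 2
    hs <- (2 * nh / (2 * nh - 1)) * hs_raw
    pb <- (p1 + p2) / 2
    ht <- 1 - sum(pb^2) + hs / (2 * nh * 2)
    nums <- c(nums, ht - hs)
    dens <- c(dens, 1 - hs)
  }
  2 * mean(nums) / mean(dens)
}

# Rousset's a-hat for one pair: identity probabilities within the two
# individuals vs between them, ratio of summed per-locus components.
rousset_oracle <- function(d, i, j) {
  num <- den <- 0
  for (l in seq_along(d$loci)) {
    gi <- c(d$a1[i, l], d$a2[i, l])
    gj <- c(d$a1[j, l], d$a2[j, l])
    if (anyNA(gi) || anyNA(gj)) next
    qw <- ((gi[1] == gi[2]) + (gj[1] == gj[2])) / 2
    qb <- 0
    for (u in 1:2) for (v in 1:2) qb <- qb + (gi[u] == gj[v]) / 4
    num <- num + qw - qb
    den <- den + 1 - qw
  }
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

# dense effective-resistance oracle: full Laplacian pseudoinverse
resistance_oracle <- function(values, neighbors = 8, cell_size = 1) {
  nr <- nrow(values); nc <- ncol(values)
  n <- nr * nc
  idx <- function(r, c) (c - 1) * nr + r
  W <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dd in list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)),
                    c(1, -1, sqrt(2)))) {
      if (neighbors == 4 && dd[3] != 1) next
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      g <- 1 / (0.5 * (values[r, c] + values[r2, c2]) * dd[3])
      W[idx(r, c), idx(r2, c2)] <- g
      W[idx(r2, c2), idx(r, c)] <- g
    }
  }
  L <- diag(rowSums(W)) - W
  Lp <- MASS::ginv(L)
  function(r1, c1, r2, c2) {
    i <- idx(r1, c1); j <- idx(r2, c2)
    Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  }
}

# brute-force patch count by repeated mask erosion (direct neighbour BFS
# over explicit pixel coordinate sets)
patch_count_oracle <- function(mask, rule = 8) {
  coords <- which(mask, arr.ind = TRUE)
  if (!nrow(coords)) return(0L)
  remaining <- seq_len(nrow(coords))
  adjacent <- function(a, b) {
    dr <- abs(coords[a, 1] - coords[b, 1])
    dc <- abs(coords[a, 2] - coords[b, 2])
    if (rule == 8) max(dr, dc) == 1 else dr + dc == 1
  }
  n <- 0L
  while (length(remaining)) {
    n <- n + 1L
    comp <- remaining[1]
    remaining <- remaining[-1]
    grew <- TRUE
    while (grew) {
      grew <- FALSE
      for (cand in remaining) {
        if (any(vapply(comp, adjacent, TRUE, b = cand))) {
          comp <- c(comp, cand)
          remaining <- setdiff(remaining, cand)
          grew <- TRUE
        }
      }
    }
  }
  n
}

# double-count rook adjacency tally for the clumpy oracle
adjacency_oracle <- function(v, code) {
  nr <- nrow(v); nc <- ncol(v)
  gii <- 0; gik <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(v[r2, c2])) next
      if (v[r, c] == code) {
        gik <- gik + 1
        if (v[r2, c2] == code) gii <- gii + 1
      }
    }
  }
  c(gii = gii, gik = gik)
}

# Exact Levene-conditional Hardy-Weinberg p for a biallelic locus by full
# enumeration of heterozygote counts given the allele counts.
hwe_exact_oracle_biallelic <- function(g1, g2) {
  n <- length(g1)
  al <- sort(unique(c(g1, g2)))
  stopifnot(length(al) == 2)
  nA <- sum(c(g1, g2) == al[1])
  nB <- 2 * n - nA
  h_obs <- sum(g1 != g2)
  # P(h | nA, n) = n! 2^h nA! nB! / ((2n)! nAA! h! nBB!)
  hs <- seq((nA %% 2), min(nA, nB), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) + h * log(2) + lfactorial(nA) + lfactorial(nB) -
      lfactorial(2 * n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, 0)
  p <- exp(logp)
  stat <- -logp                       # -log P, larger = less probable
  stat_obs <- stat[match(h_obs, hs)]
  sum(p[stat >= stat_obs - 1e-12])
}
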