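test_that("missing rate bookkeeping matches hand-counted fractions", {
  # 14,916 calls with 107 missing -> 0.717 % to three significant figures
  d1 <- genotype_dataset(paste0("i", 1:1243), paste0("L", 1:12),
                         a1 = matrix(1L, 1243, 12), a2 = matrix(2L, 1243, 12),
                         cell = rep("c1", 1243))
  miss <- arrayInd(1:107, dim(d1$a1))
  d1$a1[miss] <- NA; d1$a2[miss] <- NA
  expect_equal(nrow(d1$a1) * ncol(d1$a1), 14916)
  expect_equal(signif(100 * missing_rate(d1), 3), 0.717)
  # no missing -> 0
  d0 <- random_dataset(miss = 0)
  expect_equal(missing_rate(d0), 0)
  # dataset rate equals locus-weighted mean of per-individual rates
  dm <- random_dataset(miss = 0.15, seed = 3)
  expect_equal(missing_rate(dm), mean(missing_rate(dm, "individual")))
  expect_error(missing_rate(genotype_dataset(character(0), "L1",
                                             matrix(NA_integer_, 0, 1),
                                             matrix(NA_integer_, 0, 1),
                                             character(0))),
               "empty")
})

test_that("the individual missingness gate is strictly below the threshold", {
  a1 <- matrix(1L, 3, 10); a2 <- matrix(2L, 3, 10)
  a1[1, 1:3] <- NA; a2[1, 1:3] <- NA      # exactly 0.30 -> removed
  a1[2, 1:2] <- NA; a2[2, 1:2] <- NA      # 0.20 -> retained
  a1[3, ] <- NA; a2[3, ] <- NA            # all missing -> removed
  d <- genotype_dataset(c("x", "y", "z"), paste0("L", 1:10), a1, a2,
                        rep("c1", 3))
  kept <- filter_individuals(d, 0.3)
  expect_identical(kept$individuals, "y")
  # idempotent
  expect_identical(filter_individuals(kept, 0.3)$individuals, "y")
})

test_that("Monte-Carlo HWE test matches full enumeration on a tiny table", {
  # 5 individuals, all heterozygous A/B: maximal heterozygote excess
  d <- genotype_dataset(paste0("i", 1:5), "L1",
                        matrix(1L, 5, 1), matrix(2L, 5, 1), rep("c1", 5))
  exact <- hwe_exact_oracle_biallelic(d$a1[, 1], d$a2[, 1])
  mc <- hwe_exact_test(d, "c1", 1, n_perm = 20000, seed = 9)
  expect_lt(abs(mc$p - exact), 3 * sqrt(exact * (1 - exact) / 20000) + 1e-3)
  # a second, non-extreme configuration: 3 het + 2 AA hom
  d2 <- genotype_dataset(paste0("i", 1:5), "L1",
                         matrix(c(1L, 1L, 1L, 1L, 1L), 5, 1),
                         matrix(c(2L, 2L, 2L, 1L, 1L), 5, 1), rep("c1", 5))
  exact2 <- hwe_exact_oracle_biallelic(d2$a1[, 1], d2$a2[, 1])
  mc2 <- hwe_exact_test(d2, "c1", 1, n_perm = 20000, seed = 9)
  expect_lt(abs(mc2$p - exact2), 3 * sqrt(exact2 * (1 - exact2) / 20000) + 1e-3)
})

test_that("HWE test flags monomorphic loci and finds large-sample excess het", {
  dm <- genotype_dataset(paste0("i", 1:6), "L1",
                         matrix(1L, 6, 1), matrix(1L, 6, 1), rep("c1", 6))
  res <- hwe_exact_test(dm, "c1", 1, n_perm = 200, seed = 1)
  expect_equal(res$p, 1)
  expect_true(res$monomorphic)
  # 20 individuals all A/B heterozygous: strong deviation
  dh <- genotype_dataset(paste0("i", 1:20), "L1",
                         matrix(1L, 20, 1), matrix(2L, 20, 1), rep("c1", 20))
  expect_lt(hwe_exact_test(dh, "c1", 1, n_perm = 2000, seed = 2)$p, 0.01)
})

test_that("HWE test keeps its size under data simulated at equilibrium", {
  # genotype draws at exact HW proportions should rarely be rejected
  rej <- 0
  for (r in 1:60) {
    d <- withr::with_seed(100 + r, {
      p <- runif(1, 0.2, 0.8)
      g1 <- rbinom(200, 1, p) + 1L
      g2 <- rbinom(200, 1, p) + 1L
      genotype_dataset(paste0("i", 1:200), "L1", matrix(g1), matrix(g2),
                       rep("c1", 200))
    })
    if (hwe_exact_test(d, "c1", 1, n_perm = 199, seed = r)$p <= 0.05)
      rej <- rej + 1
  }
  expect_lt(rej / 60, 0.15)
})

test_that("Benjamini-Yekutieli decisions follow the hand-computed step-up", {
  # single test reduces to the raw level
  expect_true(fdr_threshold(0.04, 0.05)$reject)
  expect_false(any(fdr_threshold(rep(1, 8), 0.05)$reject))
  # m = 10, c(10) = sum(1/i) ~ 2.9290: only the 0.001 test survives
  p <- c(0.001, rep(0.2, 9))
  res <- fdr_threshold(p, 0.05)
  expect_identical(which(res$reject), 1L)
  expect_equal(res$cutoff, 0.001)
  # BY never rejects more than BH at the same level
  for (s in 1:20) {
    pv <- withr::with_seed(s, runif(12)^2)
    by <- sum(fdr_threshold(pv, 0.05)$reject)
    bh <- sum(p.adjust(pv, "BH") <= 0.05)
    expect_lte(by, bh)
  }
})

test_that("Brookfield null-allele estimator evaluates its closed form", {
  # Ho = 0, He = 0.5 -> (0.5 - 0)/(1 + 0.5) = 1/3
  d <- genotype_dataset(paste0("i", 1:20), "L1",
                        matrix(rep(c(1L, 2L), 10)), matrix(rep(c(1L, 2L), 10)),
                        rep("c1", 20))
  est <- null_allele_freq(d, "c1", 1)
  h <- heterozygosities(d, "c1", 1)
  expect_equal(h$Ho, 0)
  expect_equal(est$estimate, (h$He - 0) / (1 + h$He))
  expect_equal(est$estimate, 0.3333, tolerance = 0.02)
  # Ho >= He -> clipped at zero
  dh <- genotype_dataset(paste0("i", 1:10), "L1",
                         matrix(1L, 10, 1), matrix(2L, 10, 1), rep("c1", 10))
  expect_equal(null_allele_freq(dh, "c1", 1)$estimate, 0)
  # monomorphic -> flagged zero
  dm <- genotype_dataset(paste0("i", 1:5), "L1",
                         matrix(1L, 5, 1), matrix(1L, 5, 1), rep("c1", 5))
  expect_true(null_allele_freq(dm, "c1", 1)$monomorphic)
})

test_that("the HWE screen flags loci rejected in all cells and skips LE", {
  withr::with_seed(5, {
    n <- 40
    # locus 1: all heterozygous everywhere (consistent deviation)
    a1 <- cbind(rep(1L, 2 * n), sample.int(4, 2 * n, TRUE))
    a2 <- cbind(rep(2L, 2 * n), sample.int(4, 2 * n, TRUE))
    d <- genotype_dataset(paste0("i", 1:(2 * n)), c("bad", "ok"), a1, a2,
                          rep(c("c1", "c2"), each = n))
    scr <- hwe_screen(d, alpha = 0.013, n_perm = 500, seed = 3)
    expect_true(scr$drop[["bad"]])
    expect_false(scr$drop[["ok"]])
    expect_identical(scr$le, "not computed")
  })
})
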