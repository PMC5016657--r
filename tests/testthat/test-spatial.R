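test_that("geographic distances are Euclidean with validated labels", {
  pts <- data.frame(cell = c("a", "b"), x = c(0, 3), y = c(0, 4))
  D <- geographic_distances(pts)
  expect_equal(D["a", "b"], 5)
  same <- data.frame(cell = c("a", "b"), x = c(1, 1), y = c(2, 2))
  expect_equal(geographic_distances(same)["a", "b"], 0)
  # brute-force double loop on random points
  m <- withr::with_seed(3, matrix(runif(20), 10, 2))
  rownames(m) <- paste0("p", 1:10)
  D2 <- geographic_distances(m)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(D2[i, j], sqrt(sum((m[i, ] - m[j, ])^2)), tolerance = 1e-12)
  rownames(m)[2] <- "p1"
  expect_error(geographic_distances(m), "duplicate")
})

test_that("Mantel statistics hit exact correlations and stay symmetric", {
  A <- as.matrix(dist(withr::with_seed(1, matrix(rnorm(16), 8, 2))))
  expect_equal(mantel(A, A, n_perm = 99, seed = 1)$r, 1)
  B <- max(A) - A; diag(B) <- 0
  expect_equal(mantel(A, B, n_perm = 99, seed = 1)$r, -1)
  C <- as.matrix(dist(withr::with_seed(2, matrix(rnorm(16), 8, 2))))
  expect_equal(mantel(A, C, n_perm = 99, seed = 5)$r,
               mantel(C, A, n_perm = 99, seed = 5)$r)
  Z <- matrix(0, 8, 8)
  expect_error(mantel(A, Z, n_perm = 99), "zero variance")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  A <- as.matrix(dist(withr::with_seed(4, matrix(rnorm(24), 12, 2))))
  B <- as.matrix(dist(withr::with_seed(5, matrix(rnorm(24), 12, 2))))
  ours <- mantel(A, B, n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("partial Mantel reduces and degenerates as expected", {
  withr::with_seed(9, {
    A <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
    B <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
    C <- as.matrix(dist(matrix(rnorm(30), 15, 2))) # ~uncorrelated with A, B
    pm <- partial_mantel(A, B, C, n_perm = 99, seed = 1)
    m <- mantel(A, B, n_perm = 99, seed = 1)
    expect_lt(abs(pm$r - m$r), 0.15)
    expect_equal(partial_mantel(A, B, B, n_perm = 99, seed = 1)$r, 0)
  })
})

test_that("partial Mantel detects a constructed conditional signal", {
  hits <- 0
  for (s in 1:10) {
    withr::with_seed(700 + s, {
      n <- 15
      B <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
      C <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
      E <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
      A <- B + C + 0.3 * E
      if (partial_mantel(A, B, C, n_perm = 199, seed = s)$p < 0.05)
        hits <- hits + 1
    })
  }
  expect_gte(hits, 9)
})

test_that("barrier indicator codes cross-river pairs as 1", {
  cells <- data.frame(cell = c("a", "b", "c"), side = c("N", "N", "S"))
  M <- barrier_indicator(cells)
  expect_equal(M["a", "b"], 0)
  expect_equal(M["a", "c"], 1)
  expect_equal(M["b", "c"], 1)
  expect_equal(sum(M), 4)          # two unordered pairs, symmetric
  same <- data.frame(cell = c("a", "b"), side = c("N", "N"))
  expect_equal(sum(barrier_indicator(same)), 0)
  expect_error(barrier_indicator(data.frame(cell = "a", x = 1)), "side")
  # random labels vs brute force
  withr::with_seed(12, {
    lab <- sample(c("N", "S"), 9, TRUE)
    cl <- data.frame(cell = paste0("c", 1:9), side = lab)
    M2 <- barrier_indicator(cl)
    for (i in 1:8) for (j in (i + 1):9)
      expect_equal(M2[i, j], as.numeric(lab[i] != lab[j]))
  })
})

test_that("Rousset's a-hat matches its identity-probability oracle", {
  d <- random_dataset(n_cells = 1, n_per_cell = 5, L = 2, k = 3, seed = 31)
  A <- rousset_a(d)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(A[i, j], rousset_oracle(d, i, j), tolerance = 1e-10)
})

test_that("Rousset's a-hat orders clones below fixed-different pairs", {
  d <- genotype_dataset(paste0("i", 1:4), c("L1", "L2"),
                        a1 = rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(3L, 3L)),
                        a2 = rbind(c(1L, 1L), c(1L, 1L), c(2L, 2L), c(3L, 3L)),
                        cell = rep("c1", 4))
  A <- rousset_a(d)
  expect_lt(A[1, 2], A[3, 4])            # clones < fixed-different
  # identical individuals -> exchangeable pairwise values
  di <- genotype_dataset(paste0("i", 1:4), c("L1", "L2"),
                         a1 = matrix(1L, 4, 2), a2 = matrix(2L, 4, 2),
                         cell = rep("c1", 4))
  Ai <- rousset_a(di)
  expect_equal(length(unique(round(landgen:::ut(unclass(Ai)), 12))), 1)
})

test_that("spatial autocorrelation finds clustered clones and bins pairs once", {
  withr::with_seed(21, {
    # two clusters of clones 1 km apart
    n <- 12
    a1 <- rbind(matrix(1L, n, 4), matrix(3L, n, 4))
    a2 <- rbind(matrix(2L, n, 4), matrix(4L, n, 4))
    xy <- rbind(cbind(runif(n, 0, 50), runif(n, 0, 50)),
                cbind(runif(n, 1000, 1050), runif(n, 1000, 1050)))
    d <- genotype_dataset(paste0("i", 1:(2 * n)), paste0("L", 1:4), a1, a2,
                          rep("c1", 2 * n), xy)
    ac <- spatial_autocorrelation(d, class_width_m = 100, max_dist_m = 2000,
                                  n_perm = 199, n_boot = 99, seed = 2)
    first <- which(ac$n_pairs > 0)[1]
    expect_gt(ac$r[first], 0)
    expect_gt(ac$r[first], ac$null_hi[first])
    # every within-bound pair lands in exactly one class
    npairs_total <- sum(ac$n_pairs)
    geo <- as.matrix(dist(xy))
    expect_equal(npairs_total, sum(geo[upper.tri(geo)] <= 2000))
  })
})

test_that("spatial autocorrelation is flat for shuffled coordinates and flags clones", {
  withr::with_seed(31, {
    d <- random_dataset(n_cells = 1, n_per_cell = 40, L = 5, k = 5, seed = 77)
    ac <- spatial_autocorrelation(d, class_width_m = 250, max_dist_m = 1500,
                                  n_perm = 199, n_boot = 99, seed = 3)
    occupied <- ac$n_pairs >= 5
    inside <- ac$r[occupied] >= ac$null_lo[occupied] &
      ac$r[occupied] <= ac$null_hi[occupied]
    expect_gte(mean(inside), 0.5)
    # all identical genotypes: degenerate, r reported 0
    di <- genotype_dataset(paste0("i", 1:12), "L1", matrix(1L, 12, 1),
                           matrix(1L, 12, 1), rep("c1", 12),
                           cbind(runif(12, 0, 500), runif(12, 0, 500)))
    aci <- spatial_autocorrelation(di, class_width_m = 250, max_dist_m = 1000,
                                   n_perm = 49, n_boot = 49, seed = 1)
    expect_true(attr(aci, "degenerate"))
    expect_true(all(aci$r == 0))
  })
})
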