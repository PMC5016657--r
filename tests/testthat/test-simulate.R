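test_that("generated landscapes hit their class proportions and are seeded", {
  land <- generate_landscape(100, 100, seed = 3)
  pr <- mean(land$values == landcover_classes()["forest"])
  expect_gte(pr, 0.06); expect_lte(pr, 0.10)
  # exact-to-the-pixel rank thresholding
  expect_equal(pr, 0.08, tolerance = 2e-4)
  land2 <- generate_landscape(100, 100, seed = 3)
  expect_identical(land$values, land2$values)
  # degenerate single-class proportions
  solid <- generate_landscape(20, 20, class_proportions = c(
    forest = 1, wetland = 0, urban = 0, water = 0, grassland = 0,
    agriculture = 0), seed = 1)
  expect_true(all(solid$values == landcover_classes()["forest"]))
  expect_error(generate_landscape(10, 10, class_proportions = c(
    forest = 0.5, wetland = 0, urban = 0, water = 0, grassland = 0,
    agriculture = 0), seed = 1), "sum to 1")
  # larger patchiness -> fewer, larger patches of the same class budget
  p_small <- patch_density(generate_landscape(80, 80, patchiness = 2,
                                              seed = 5), 6)
  p_big <- patch_density(generate_landscape(80, 80, patchiness = 10,
                                            seed = 5), 6)
  expect_lt(p_big, p_small)
})

test_that("study-cell placement respects separation and labels sides", {
  land <- generate_landscape(100, 100, seed = 9)
  cells <- place_cells(land, 10, min_separation_px = 20, seed = 4)
  expect_equal(nrow(cells), 10)
  px <- world_to_pixel(land, cells$x, cells$y)
  dmat <- as.matrix(dist(px))
  expect_gte(min(dmat[upper.tri(dmat)]), 20)
  expect_setequal(unique(cells$side), c("N", "S"))
  expect_error(place_cells(land, 2, min_separation_px = 1000, seed = 1,
                           max_tries = 200), "could not place")
})

test_that("metapopulation simulation is reproducible and truth-tagged", {
  tr <- scenario_preset("specialist", n_rows = 60, n_cols = 60, n_cells = 4,
                        n_loci = 4, sample_sizes = 10, seed = 31)
  d1 <- simulate_metapopulation(tr)
  d2 <- simulate_metapopulation(tr)
  expect_identical(d1$a1, d2$a1)
  expect_identical(d1$coords, d2$coords)
  expect_s3_class(attr(d1, "truth"), "simulation_truth")
  Dres <- attr(d1, "resistance_d")
  expect_equal(rownames(Dres), tr$cells$cell)
  expect_equal(length(d1$individuals), 40)
})

test_that("panmixia (beta = 0) leaves essentially no structure", {
  tr <- withr::with_seed(77, {
    land <- generate_landscape(60, 60, patchiness = 6, seed = 8)
    cells <- place_cells(land, 4, min_separation_px = 15, seed = 9)
    simulation_truth(land, cells, "IBD", beta = 0, m_total = 0.5,
                     generations = 20, Ne = 5000, n_loci = 8, n_alleles = 6,
                     sample_sizes = 50, missing_rate = 0, seed = 10)
  })
  d <- simulate_metapopulation(tr)
  f <- pairwise_fst(d)
  expect_true(all(abs(landgen:::ut(f$est)) < 0.01))
})

test_that("zero migration drives demes toward fixation and high F_ST", {
  tr <- withr::with_seed(78, {
    land <- generate_landscape(40, 40, patchiness = 4, seed = 1)
    cells <- place_cells(land, 3, min_separation_px = 12, seed = 2,
                         diversify = 1)
    simulation_truth(land, cells, "IBD", beta = 1e9, m_total = 0,
                     generations = 150, Ne = 25, n_loci = 8, n_alleles = 4,
                     sample_sizes = 25, missing_rate = 0,
                     deme_spacing_px = 15, seed = 3)
  })
  d <- suppressWarnings(simulate_metapopulation(tr))
  f <- pairwise_fst(d)
  expect_gt(mean(landgen:::ut(f$est)), 0.5)
})

test_that("stronger landscape coupling raises the distance-F_ST correlation", {
  rank_r <- function(bs, seed) {
    tr <- scenario_preset("specialist", n_rows = 80, n_cols = 80,
                          n_cells = 6, n_loci = 6, sample_sizes = 20,
                          seed = seed)
    tr$beta_scale <- bs
    if (bs == 0) tr$beta <- 0
    d <- simulate_metapopulation(tr)
    f <- pairwise_fst(d)
    Dres <- attr(d, "resistance_d")
    cor(landgen:::ut(f$est), landgen:::ut(as.matrix(Dres)),
        method = "spearman")
  }
  seeds <- 8100 + 1:6
  r0 <- mean(vapply(seeds, function(s) rank_r(0, s), 0))
  r2 <- mean(vapply(seeds, function(s) rank_r(2, s), 0))
  expect_gt(r2, r0 + 0.2)
})

test_that("within-cell lattice datasets show distance-decaying similarity", {
  d <- simulate_lattice_individuals(80, dispersal_sigma_m = 250, L = 10,
                                    k = 6, extent_m = 3000, seed = 5)
  d2 <- simulate_lattice_individuals(80, dispersal_sigma_m = 250, L = 10,
                                     k = 6, extent_m = 3000, seed = 5)
  expect_identical(d$a1, d2$a1)
  A <- rousset_a(d)
  geo <- as.matrix(dist(d$coords))
  ok <- is.finite(landgen:::ut(unclass(A)))
  m <- cor(landgen:::ut(unclass(A))[ok], log(landgen:::ut(geo)[ok] + 1))
  expect_gt(m, 0.1)
  # near-infinite dispersal scale removes the spatial signal
  dflat <- simulate_lattice_individuals(80, dispersal_sigma_m = 1e7, L = 10,
                                        k = 6, extent_m = 3000, seed = 6)
  Af <- rousset_a(dflat)
  okf <- is.finite(landgen:::ut(unclass(Af)))
  mf <- cor(landgen:::ut(unclass(Af))[okf],
            landgen:::ut(as.matrix(dist(dflat$coords)))[okf])
  expect_lt(abs(mf), 0.12)
})

test_that("simulated within-cell IBD yields positive Mantel tests repeatedly", {
  hits <- 0
  for (s in 1:10) {
    d <- simulate_lattice_individuals(80, dispersal_sigma_m = 250, L = 10,
                                      k = 6, extent_m = 3000,
                                      seed = 8300 + s)
    A <- unclass(rousset_a(d))
    A[!is.finite(A)] <- max(A[is.finite(A)])
    diag(A) <- 0
    G <- log(as.matrix(dist(d$coords)) + 1)
    diag(G) <- 0
    m <- mantel(A, G, n_perm = 199, seed = s)
    if (m$p < 0.05 && m$r > 0) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
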