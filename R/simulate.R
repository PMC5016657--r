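# Synthetic landscapes, study cells, and metapopulation genotypes with known
# ground truth. The generator provides inputs with the statistical structure
# the analysis assumes: a hidden resistance surface drives between-cell
# migration ("specialist" regime), or no structure at all ("generalist").

# Smooth a white-noise field with a separable Gaussian kernel (reflected
# edges); sigma in pixels controls patch size.
.smooth_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(m) {
    # filter columns then rows with edge reflection
    idx <- c(rev(seq_len(hw)), seq_len(nrow(m)),
             nrow(m) - seq_len(hw) + 1L)
    mp <- m[idx, , drop = FALSE]
    f <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    f[hw + seq_len(nrow(m)), , drop = FALSE]
  }
  z <- pad_filter(z)
  t(pad_filter(t(z)))
}

#' Generate a synthetic categorical land-cover raster
#'
#' A Gaussian-smoothed random field is thresholded at the quantiles implied
#' by the target class proportions (rank-based, so realized proportions are
#' exact to the pixel). Larger `patchiness` (the smoothing scale in pixels)
#' yields larger contiguous patches.
#'
#' @param n_rows,n_cols raster dimensions.
#' @param class_proportions named numeric vector over
#'   `names(landcover_classes())`, summing to 1.
#' @param patchiness smoothing sigma in pixels (> 0).
#' @param seed integer seed.
#' @param cell_size pixel size in metres (default 30, the land-cover grid of
#'   the study system).
#' @return a [land_raster()] of class codes.
#' @export
generate_landscape <- function(n_rows, n_cols,
                               class_proportions = c(
                                 forest = 0.08, wetland = 0.04, urban = 0.10,
                                 water = 0.06, grassland = 0.12,
                                 agriculture = 0.60),
                               patchiness = 6, seed = 1, cell_size = 30) {
  stopifnot(patchiness > 0)
  pr <- class_proportions[names(class_proportions) %in%
                            names(landcover_classes())]
  if (any(pr < 0) || abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must be non-negative and sum to 1")
  codes <- landcover_classes()[names(class_proportions)]
  v <- with_seed(seed, .smooth_field(n_rows, n_cols, patchiness))
  rk <- rank(v, ties.method = "first")
  npix <- n_rows * n_cols
  cuts <- round(cumsum(class_proportions) * npix)
  cls <- codes[findInterval(rk, c(0, cuts), left.open = TRUE,
                            rightmost.closed = TRUE)]
  land_raster(matrix(as.numeric(cls), n_rows, n_cols), cell_size)
}

#' Place study-cell focal points on a raster
#'
#' Rejection sampling of focal points on non-nodata pixels with a minimum
#' pairwise separation. By default several candidate placements are drawn
#' and the one maximising the diversity of local land-cover composition
#' across cells is kept, mirroring study designs that stratify sampling
#' across cover types; `diversify = FALSE` keeps the first valid placement.
#' A horizontal split line through the raster middle assigns the
#' side-of-barrier label (`N` / `S`).
#'
#' @param raster a [land_raster()].
#' @param n_cells number of study cells.
#' @param min_separation_px minimum pairwise separation in pixels.
#' @param seed integer seed.
#' @param max_tries bounded retries before giving up.
#' @param diversify number of candidate placements scored for land-cover
#'   diversity (1 = plain uniform placement).
#' @return data.frame: `cell`, `x`, `y`, `side`.
#' @export
place_cells <- function(raster, n_cells, min_separation_px, seed = 1,
                        max_tries = 5000, diversify = 15) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  one_set <- function() {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n_cells) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place ", n_cells, " cells at separation ",
             min_separation_px, " after ", max_tries, " tries")
      rc <- c(sample.int(nr, 1), sample.int(nc, 1))
      if (is.na(raster$values[rc[1], rc[2]])) next
      if (nrow(pts) &&
          min(sqrt(rowSums(sweep(pts, 2, rc)^2))) < min_separation_px) next
      pts <- rbind(pts, rc)
    }
    pts
  }
  # local land-cover composition in a window around a focal pixel
  comp <- function(rc, hw = 6) {
    r1 <- max(1, rc[1] - hw); r2 <- min(nr, rc[1] + hw)
    c1 <- max(1, rc[2] - hw); c2 <- min(nc, rc[2] + hw)
    v <- raster$values[r1:r2, c1:c2]
    tabulate(v[!is.na(v)], nbins = max(raster$values, na.rm = TRUE)) /
      sum(!is.na(v))
  }
  with_seed(seed, {
    best <- NULL; best_score <- -Inf
    for (s in seq_len(max(1, diversify))) {
      pts <- one_set()
      cps <- t(apply(pts, 1, comp))
      score <- mean(stats::dist(cps))   # spread of local compositions
      if (score > best_score) { best <- pts; best_score <- score }
    }
    w <- pixel_to_world(raster, best[, 1], best[, 2])
    data.frame(cell = sprintf("c%02d", seq_len(n_cells)),
               x = w[, 1], y = w[, 2],
               side = ifelse(best[, 1] <= nr / 2, "N", "S"),
               stringsAsFactors = FALSE)
  })
}

#' Simulation ground truth
#'
#' Bundles the generator's parameters: the landscape, the true surface
#' hypothesis, migration scale `beta` (per unit resistance distance), total
#' emigration rate, generations, effective size per deme, locus count and
#' alleles per locus, per-cell sample sizes, missingness and seed. The same
#' truth object always regenerates the identical dataset.
#'
#' @param landscape a [land_raster()] of class codes.
#' @param cells data.frame from [place_cells()].
#' @param surface true [surface_hypothesis()] (or `"IBD"`/`"IBB"`).
#' @param beta migration distance-decay per unit resistance distance;
#'   0 = panmixia; `NULL` = auto, `beta_scale / median nearest-deme
#'   resistance distance` (a local stepping-stone kernel), resolved when the
#'   simulation runs and recorded on the output.
#' @param beta_scale decay multiplier used when `beta = NULL`.
#' @param m_total total emigration fraction per generation.
#' @param generations forward generations of drift.
#' @param Ne effective diploid size per deme.
#' @param n_loci,n_alleles loci and alleles per locus.
#' @param sample_sizes per-cell sampled individuals (recycled).
#' @param missing_rate uniform genotype missingness.
#' @param deme_spacing_px lattice spacing (pixels) of the demes carrying the
#'   forward simulation; the study cells sample the deme at their focal
#'   point. Smaller spacing = finer stepping-stone structure.
#' @param seed integer seed.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(landscape, cells, surface = "IBD", beta = 0,
                             m_total = 0.2, generations = 100, Ne = 200,
                             n_loci = 10, n_alleles = 8,
                             sample_sizes = 30, missing_rate = 0.01,
                             deme_spacing_px = 12, beta_scale = 2,
                             seed = 1) {
  structure(list(landscape = landscape, cells = cells, surface = surface,
                 beta = beta, beta_scale = beta_scale,
                 m_total = m_total, generations = generations,
                 Ne = Ne, n_loci = n_loci, n_alleles = n_alleles,
                 sample_sizes = rep_len(sample_sizes, nrow(cells)),
                 missing_rate = missing_rate,
                 deme_spacing_px = deme_spacing_px, seed = seed),
            class = "simulation_truth")
}

#' Simulate a metapopulation genotype dataset from a truth object
#'
#' Forward Wright-Fisher simulation over a lattice of demes spanning the
#' landscape (spacing `deme_spacing_px`; the population is continuous, not
#' confined to the sampled cells). Migration between demes follows
#' `m_ij proportional to exp(-beta * d_ij)` with `d_ij` the circuit-theory
#' resistance distances between deme locations under the true surface, rows
#' normalised to the total emigration rate `m_total` (diagonal
#' `1 - m_total`); `beta = 0` gives landscape-blind uniform mixing.
#' Ancestral allele frequencies are Dirichlet(1,...,1) per locus; each
#' generation the migration-mixed frequencies are resampled multinomially
#' (2 Ne draws per deme). After `generations` generations each study cell
#' samples individuals by Hardy-Weinberg draws from the frequencies of the
#' deme at its focal point; uniform missingness is applied and coordinates
#' are jittered around the focal point. Demes isolated by infinite
#' resistance receive no migrants (warning).
#'
#' @param truth a [simulation_truth()].
#' @return a [genotype_dataset()]; attributes `truth` and `resistance_d`
#'   (the true between-cell resistance-distance matrix).
#' @export
simulate_metapopulation <- function(truth) {
  cells <- truth$cells
  k <- nrow(cells)
  surf <- build_resistance_surface(truth$landscape, truth$surface)
  # deme lattice on non-nodata pixels; every study-cell focal pixel is a deme
  nr <- nrow(truth$landscape$values); ncl <- ncol(truth$landscape$values)
  sp <- truth$deme_spacing_px
  gr <- expand.grid(row = seq(ceiling(sp / 2), nr, by = sp),
                    col = seq(ceiling(sp / 2), ncl, by = sp))
  keepd <- !is.na(truth$landscape$values[cbind(gr$row, gr$col)])
  gr <- gr[keepd, , drop = FALSE]
  dw <- pixel_to_world(truth$landscape, gr$row, gr$col)
  focal_px <- world_to_pixel(truth$landscape, cells$x, cells$y)
  demes <- data.frame(cell = c(sprintf("d%04d", seq_len(nrow(gr))),
                               cells$cell),
                      x = c(dw[, 1], cells$x), y = c(dw[, 2], cells$y))
  nd <- nrow(demes)
  cell_idx <- nrow(gr) + seq_len(k)
  Dall <- resistance_distance(surf, demes)
  Dres <- dist_matrix(unclass(Dall)[cell_idx, cell_idx, drop = FALSE],
                      "resistance")
  # Stepping-stone migration: exchange is restricted to lattice-neighbour
  # demes (within 1.6 lattice spacings), with weights exp(-beta * d_ij) on
  # the local resistance distance. Differentiation then accumulates along
  # the landscape, the regime in which effective resistance predicts
  # genetic distance. beta = 0 removes all landscape dependence
  # (uniform global mixing).
  Dw <- unclass(Dall)
  diag(Dw) <- NA
  geo_d <- as.matrix(stats::dist(cbind(demes$x, demes$y)))
  step <- truth$deme_spacing_px * truth$landscape$cell_size
  adj <- geo_d > 0 & geo_d <= 1.6 * step
  if (is.null(truth$beta)) {
    nb_d <- Dw[adj & is.finite(Dw)]
    truth$beta <- truth$beta_scale / stats::median(nb_d[nb_d > 0])
  }
  if (truth$beta == 0) {
    # landscape-blind: uniform global mixing at rate m_total
    M <- matrix(1, nd, nd)
    diag(M) <- 0
    M <- truth$m_total * M / rowSums(M)
    diag(M) <- 1 - truth$m_total
  } else {
    M <- matrix(0, nd, nd)
    sel <- adj & is.finite(Dw)
    M[sel] <- exp(-truth$beta * Dw[sel])
    if (any(rowSums(M) == 0))
      warning("isolated demes receive no migrants")
    if (truth$m_total == 0 || all(M == 0)) {
      M <- diag(nd)                 # complete isolation: pure drift
    } else {
    # absolute rates: one global scale puts the median deme at m_total
    # total emigration, so demes in hostile matrix genuinely exchange less
    # (and drift more) than demes in permeable habitat
    rs <- rowSums(M)
    sc <- truth$m_total / stats::median(rs[rs > 0])
    M <- M * sc
    rs <- rowSums(M)
    over <- rs > 0.9
    if (any(over)) M[over, ] <- 0.9 * M[over, , drop = FALSE] / rs[over]
    diag(M) <- 1 - rowSums(M)
    }
  }
  with_seed(truth$seed, {
    L <- truth$n_loci
    na <- truth$n_alleles
    two_ne <- 2 * truth$Ne
    freqs <- lapply(seq_len(L), function(l) {
      g <- stats::rgamma(na, 1)
      p0 <- g / sum(g)
      matrix(p0, nd, na, byrow = TRUE)
    })
    for (gen in seq_len(truth$generations)) {
      for (l in seq_len(L)) {
        mixed <- M %*% freqs[[l]]
        mixed <- pmax(mixed, 0)
        mixed <- mixed / rowSums(mixed)
        # multinomial drift per deme, vectorised as binomial splits
        counts <- matrix(0L, nd, na)
        rem <- rep.int(two_ne, nd)
        ptail <- rep(1, nd)
        for (a in seq_len(na - 1)) {
          pa <- ifelse(ptail > 0, pmin(pmax(mixed[, a] / ptail, 0), 1), 0)
          counts[, a] <- stats::rbinom(nd, rem, pa)
          rem <- rem - counts[, a]
          ptail <- ptail - mixed[, a]
        }
        counts[, na] <- rem
        freqs[[l]] <- counts / two_ne
      }
    }
    ns <- truth$sample_sizes
    ntot <- sum(ns)
    A1 <- A2 <- matrix(NA_integer_, ntot, L)
    cellv <- rep(cells$cell, ns)
    row0 <- 0
    jit <- truth$landscape$cell_size * 15
    coords <- matrix(NA_real_, ntot, 2)
    for (ci in seq_len(k)) {
      rows <- row0 + seq_len(ns[ci])
      di <- cell_idx[ci]
      for (l in seq_len(L)) {
        p <- freqs[[l]][di, ]
        if (sum(p) == 0) p <- rep(1 / na, na)
        A1[rows, l] <- sample.int(na, ns[ci], replace = TRUE, prob = p)
        A2[rows, l] <- sample.int(na, ns[ci], replace = TRUE, prob = p)
      }
      coords[rows, 1] <- cells$x[ci] + stats::rnorm(ns[ci], 0, jit)
      coords[rows, 2] <- cells$y[ci] + stats::rnorm(ns[ci], 0, jit)
      row0 <- row0 + ns[ci]
    }
    if (truth$missing_rate > 0) {
      miss <- matrix(stats::runif(ntot * L) < truth$missing_rate, ntot, L)
      A1[miss] <- NA; A2[miss] <- NA
    }
    d <- genotype_dataset(sprintf("ind%05d", seq_len(ntot)),
                          sprintf("loc%02d", seq_len(L)),
                          A1, A2, cellv, coords)
    attr(d, "truth") <- truth
    attr(d, "resistance_d") <- Dres
    d
  })
}

#' Simulate within-cell isolation-by-distance at the individual level
#'
#' Individuals are placed uniformly on a square plane; each locus's local
#' allele frequencies follow spatially autocorrelated Gaussian fields
#' (softmax-transformed) with correlation scale `dispersal_sigma_m`, so
#' genotype similarity decays with distance. Tiny `dispersal_sigma_m` gives
#' clustered near-clones; very large values give no spatial structure.
#'
#' @param n_individuals number of individuals (>= 20).
#' @param dispersal_sigma_m spatial correlation scale in metres.
#' @param L loci; `k` alleles per locus.
#' @param k alleles per locus.
#' @param extent_m side of the square study cell (default 4800 m, a 23 km^2
#'   cell).
#' @param amplitude field amplitude: larger = stronger local fixation.
#' @param seed integer seed.
#' @return a [genotype_dataset()] with a single cell label `"cell1"`.
#' @export
simulate_lattice_individuals <- function(n_individuals, dispersal_sigma_m,
                                         L = 10, k = 6, extent_m = 4800,
                                         amplitude = 5, seed = 1) {
  stopifnot(n_individuals >= 20)
  with_seed(seed, {
    xy <- cbind(stats::runif(n_individuals, 0, extent_m),
                stats::runif(n_individuals, 0, extent_m))
    # Gaussian-kernel mixing of random knot values gives a smooth field
    n_knots <- 100
    knots <- cbind(stats::runif(n_knots, -0.1 * extent_m, 1.1 * extent_m),
                   stats::runif(n_knots, -0.1 * extent_m, 1.1 * extent_m))
    d2 <- outer(rowSums(xy^2), rowSums(knots^2), `+`) -
      2 * xy %*% t(knots)
    W <- exp(-pmax(d2, 0) / (2 * dispersal_sigma_m^2))
    Wn <- W / pmax(rowSums(W), 1e-12)
    A1 <- A2 <- matrix(NA_integer_, n_individuals, L)
    for (l in seq_len(L)) {
      zk <- matrix(stats::rnorm(n_knots * k), n_knots, k)
      fld <- Wn %*% zk * amplitude
      pr <- exp(fld - apply(fld, 1, max))
      pr <- pr / rowSums(pr)
      for (i in seq_len(n_individuals)) {
        A1[i, l] <- sample.int(k, 1, prob = pr[i, ])
        A2[i, l] <- sample.int(k, 1, prob = pr[i, ])
      }
    }
    genotype_dataset(sprintf("ind%04d", seq_len(n_individuals)),
                     sprintf("loc%02d", seq_len(L)),
                     A1, A2, rep("cell1", n_individuals), xy)
  })
}

#' Built-in simulation scenario presets
#'
#' `"specialist"` mirrors a forest-dependent species: migration decays
#' strongly with resistance distance under a mortality-style surface with
#' highly resistant urban pixels. `"generalist"` mirrors a panmictic
#' habitat generalist: `beta = 0`, so the landscape has no effect.
#'
#' @param scenario `"specialist"` or `"generalist"`.
#' @param n_rows,n_cols landscape size in pixels.
#' @param n_cells study cells.
#' @param n_loci,n_alleles loci and alleles per locus.
#' @param sample_sizes individuals sampled per cell.
#' @param seed integer seed.
#' @return a [simulation_truth()].
#' @export
scenario_preset <- function(scenario = c("specialist", "generalist"),
                            n_rows = 150, n_cols = 150, n_cells = 12,
                            n_loci = 10, n_alleles = 12, sample_sizes = 30,
                            seed = 1) {
  scenario <- match.arg(scenario)
  land <- generate_landscape(n_rows, n_cols, seed = child_seed(seed, "land"),
                             patchiness = n_rows / 7.5)
  cells <- place_cells(land, n_cells,
                       min_separation_px = max(8, floor(n_rows / 6)),
                       seed = child_seed(seed, "cells"))
  if (scenario == "specialist") {
    # the true surface is the MortH candidate of the default hypothesis set
    surf <- default_hypotheses()$MortH
    simulation_truth(land, cells, surf, beta = NULL, beta_scale = 2,
                     m_total = 0.2, generations = 250, Ne = 100,
                     n_loci = n_loci,
                     n_alleles = n_alleles, sample_sizes = sample_sizes,
                     missing_rate = 0.01, seed = child_seed(seed, "geno"))
  } else {
    simulation_truth(land, cells, "IBD", beta = 0, m_total = 0.5,
                     generations = 20, Ne = 5000, n_loci = n_loci,
                     n_alleles = n_alleles, sample_sizes = sample_sizes,
                     missing_rate = 0.01, seed = child_seed(seed, "geno"))
  }
}
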