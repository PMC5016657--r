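---
title: "Methods: comparative landscape genetics with circuit-theory resistance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative landscape genetics with circuit-theory resistance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`landgen` asks how a heterogeneous landscape shapes gene flow in
terrestrial animals sampled as codominant multilocus genotypes (typically
microsatellites) across a set of study cells. The motivating system is a
fragmented agricultural basin in which a forest-dependent "specialist"
rodent and a habitat "generalist" rodent are sampled across ~28 study
cells; the analysis pipeline it implements compares competing hypotheses
about which land-cover classes impede movement, against two null
hypotheses in which only geographic distance (IBD), or distance plus open
water (IBB), matters.

The pipeline is:

1. **Quality control.** Individuals with 30% or more missing genotypes are
   removed (the gate is strict `<`), each locus is screened for
   Hardy-Weinberg deviations in every study cell with a Monte-Carlo exact
   test, the tests are corrected with the Benjamini-Yekutieli FDR at
   `alpha = 0.013`, and a locus is flagged for removal only when it is
   rejected in every cell where it is testable. Null-allele frequencies use
   Brookfield's first estimator `(He - Ho) / (1 + He)` - a closed form that
   is easy to verify - clipped at zero. Linkage-equilibrium testing is out
   of scope; the QC report marks it "not computed".
2. **Diversity and differentiation.** Per cell: sample size, mean alleles
   per locus, rarefied allelic richness (hypergeometric expectation at the
   smallest per-cell gene count), observed and Nei's unbiased expected
   heterozygosity, and multilocus Weir-Cockerham *F*~IS~ with a
   bootstrap-over-loci CI. Between cells: pairwise Weir-Cockerham theta and
   Jost's *D* (Nei-Chesser unbiased gene diversities, two-population
   estimator), both aggregated over loci as ratios of summed components.
   Negative point estimates are reported as computed; only the *D* CIs are
   clipped at zero. Permutation p-values re-assign individuals between the
   two cells; CIs resample loci.
3. **Isolation by distance and barrier.** Mantel tests of genetic
   differentiation against Euclidean distance between cell focal points,
   and a partial Mantel of the cross-river indicator (1 = opposite sides)
   controlling for distance. Within cells, Rousset's a-hat between
   individuals and a Smouse-Peakall multivariate autocorrelogram (100-m
   classes, bounded at 2 km) describe fine-scale structure.
4. **Landscape configuration.** Each hypothesis maps land-cover classes to
   resistances (forest = 1 for the parameterized surfaces; IBD all 1; IBB
   water 500). Pixels become nodes of a conductance graph (8 neighbours,
   diagonal edges down-weighted by sqrt(2) for geometric length; edge
   conductance is the reciprocal of the mean of the two pixel resistances),
   and the effective resistance between the pixels holding the cell focal
   points is computed by sparse Cholesky solves of the grounded graph
   Laplacian, one connected component at a time. This integrates all
   pathways rather than a single least-cost route. Disconnected pairs are
   infinite and flagged.
5. **Landscape complexity.** Within a clipped window around each cell
   (cell half-width plus a 1.6-km buffer at full scale), the proportion of
   forest, the density of 8-neighbour forest patches per 100 ha, and the
   CLUMPY aggregation index from the double-count rook adjacency table
   with the FRAGSTATS minimum-edge correction.
6. **Model selection.** For each genetic distance (theta, *D*) and each of
   the six surfaces: an MRDM of the distance matrix on the resistance
   distances plus pairwise-averaged complexity metrics, reduced by backward
   elimination; and a dbRDA of the PCoA axes on the per-cell connectivity
   index `S_i = sum_j exp(-alpha d_ij)` plus the complexity metrics, built
   by forward selection. Model CIs come from bootstrap resampling of
   individuals within cells (structure fixed from the point estimate;
   re-selection per replicate is available behind a flag). A surface is
   called *distinct* when its adjusted-R^2 CI overlaps neither null
   surface's CI; the winner is the surface with the highest adjusted R^2.

## Statistical conventions

* Permutation p-values always use the add-one form
  `(1 + #[perm >= obs]) / (n_perm + 1)`; Mantel-type tests permute the
  *second* matrix's rows and columns jointly, MRDM permutes the response
  only (coefficient tests on |t|), dbRDA permutes predictor rows. Defaults
  are one-tailed "greater" for Mantel (isolation by distance predicts a
  positive association); reference counts are 10,000 permutations and
  1,000 bootstrap replicates, scaled down in tests.
* **Global gate before selection.** Stepwise selection at a fixed
  per-term threshold inflates type-I error (the entering term is the
  minimum of several p-values). Both `mrdm_reduce()` and
  `dbrda_forward_select()` therefore first test the full candidate model
  globally and return the null model when that test is not significant -
  the standard guard adopted for forward selection in constrained
  ordination. Without it, a panmictic dataset would "find" landscape
  effects in roughly half of all runs of the 12-model design; with it the
  null model is selected throughout, as expected for a panmictic
  population.
* Adjusted R^2 is Ezekiel's `1 - (1 - R2)(n - 1)/(n - m - 1)` in both
  frameworks. MRDM predictors are z-scored over pairs so coefficients are
  comparable across surfaces; raw-scale coefficients are also kept.
* PCoA keeps eigenvalues above `1e-8 x max`; Laplacian solves use sparse
  Cholesky factorisations (exact to numerical precision, residuals far
  below the `1e-10` contract); distance-matrix symmetry is enforced at
  `1e-12`.
* Rousset's a-hat uses the identity-probability form: per locus the
  within-individual identity `Qw` (averaged over the two individuals) is
  contrasted with the between-individual identity `Qb`, and the multilocus
  estimate is `sum(Qw - Qb) / sum(1 - Qw)` - the ratio-of-sums weights
  loci by their within-individual diversity. A pair with no shared typed
  locus is missing; an identical fully homozygous pair is 0; a
  fixed-different fully homozygous pair is infinite.
* Distance classes of the autocorrelogram are half-open `[lo, hi)` with
  the last class closed at the 2-km bound; each pair contributes to
  exactly one class.
* A cell whose clipped window lacks forest has no defined CLUMPY; the
  pipeline imputes the cross-cell mean so the design stays full rank, and
  drops any metric that ends up constant.

## The synthetic study system

The field genotypes behind the motivating study were never deposited, so
the package ships a generator that reproduces the *statistical structure*
the analysis assumes, with known ground truth:

* **Landscape**: a Gaussian-smoothed random field thresholded at class
  quantiles (rank-based, proportions exact to the pixel) over six cover
  types; the default class budget is 8% forest (the basin's level), 60%
  agriculture, 10% urban, 6% water, 4% wetland, 12% grassland. `patchiness`
  sets the smoothing scale and hence patch size.
* **Study cells**: rejection-sampled focal points with a minimum
  separation; several candidate placements are scored and the one with the
  most diverse local land-cover composition is kept, mirroring the
  stratified study-cell selection of the motivating field design.
* **Genotypes**: a forward Wright-Fisher simulation over a lattice of
  demes spanning the landscape (spacing 12 px by default), not only the
  sampled cells - the population is continuous. Migration connects
  lattice-neighbour demes with weights `exp(-beta d_ij)` on their local
  circuit-theory resistance distance under the true surface; rates are
  scaled so the *median* deme emigrates `m_total` per generation, capped at
  0.9. The absolute rates matter: demes embedded in hostile cover exchange
  fewer migrants and drift more, which is exactly the regime in which
  effective resistance predicts genetic differentiation. `beta = 0`
  replaces the kernel with uniform global mixing (panmixia). Allele
  frequencies start from a Dirichlet(1,...,1) draw per locus and drift by
  multinomial resampling of 2Ne genes per deme per generation; study cells
  then sample individuals by Hardy-Weinberg draws from the deme at their
  focal point, with uniform missingness and jittered coordinates.

  An earlier design that treated the sampled cells themselves as the only
  demes, with a global kernel over their pairwise effective resistances,
  was abandoned: effective resistance in two dimensions grows only
  logarithmically with separation, so a global kernel is nearly flat, a
  dozen fully-coupled demes equilibrate into near-uniform differentiation,
  and the realized F_ST carried almost no imprint of the surface. The
  lattice stepping-stone is the standard construction in landscape-genetics
  simulators and makes the true surface genuinely recoverable.
* **Presets.** `scenario_preset("specialist")`: the true surface is the
  high-urban-mortality hypothesis (MortH), `Ne = 100`, 250 generations,
  `m_total = 0.2`, decay `beta = 2 / median` neighbour resistance distance,
  10 loci x 12 alleles, 30 individuals per cell, 1% missingness, on a
  150 x 150 raster with 12 cells. These values were calibrated once against
  the published chipmunk ranges (pairwise theta about 0.01-0.13 and strong
  isolation by distance) and then frozen. `scenario_preset("generalist")`:
  `beta = 0`, `Ne = 5000`, 20 generations, mirroring a panmictic
  white-footed-mouse-like population.
* The default surface parameter tables keep the two published anchors
  (forest = 1 everywhere; wetland = 5 on the movement surfaces; water = 500
  on IBB) and fill the remaining classes with illustrative synthetic
  values; real analyses supply species-specific tables via
  `read_surface_params()`.

What the generator does *not* emulate: stepwise mutation (loci are k-allele
Wright-Fisher; fine for the short horizons simulated), sex-biased or
long-distance dispersal, temporal variation in the landscape, genotyping
artefacts beyond uniform missingness, and within-cell spatial pedigree
structure in the metapopulation sampler (the separate
`simulate_lattice_individuals()` provides within-cell isolation by distance
for the fine-scale tests). Passing tests on these simulations therefore
validate the estimators and the inference machinery, not every property of
real microsatellite surveys.

## Problem sizes and open choices

Test and acceptance runs use deliberately modest sizes chosen as a
desk-scale version of the study design: 150 x 150 rasters (12 cells, 10
loci, 30 individuals per cell, 999 permutations, 200 bootstrap replicates)
for end-to-end recovery, 20 replicates per scenario, and 500 null
replicates for calibration checks. The reference counts for a real analysis
remain 10,000 permutations and 1,000 bootstraps.

Choices the source design left open, and what this package does:

* Rarefaction depth for allelic richness: the smallest per-cell gene count,
  per locus (configurable).
* Connectivity decay `alpha`: `1 / median` off-diagonal resistance distance
  by default, recorded on the result.
* Within-cell Mantel distance transform: raw distance by default; the
  simulation tests use `log` distance where the generating process is
  multiplicative.
* Study cells enter the circuit as the single pixel containing their focal
  coordinate (deterministic); shorting a full cell polygon into one node is
  a documented alternative not enabled by default.
* Bootstrap replicates refit the *fixed* reduced model; re-running
  selection inside each replicate is available (`reselect = TRUE`) but off
  by default, because re-selection mixes model uncertainty into interval
  width and the comparison rule assumes a common structure.
* Pattern metrics accept any raster resolution and record the pixel size;
  the reference analysis mixed 3-m pattern rasters with 30-m resistance
  rasters, and this implementation simply computes on whatever grid it is
  given.

## Known limitations

* The dbRDA connectivity index compresses a pairwise resistance structure
  into one node-level covariate; with only ~12 cells its power is low even
  when the pairwise signal is strong. The MRDM path, which models the
  pairwise response directly, is the sharper instrument for surface
  comparison at small cell counts, and is what the recovery analyses use.
* Effective-resistance saturation means very distant pairs are barely
  distinguished by the circuit metric; inference rests mostly on near- and
  mid-range pairs.
* Monte-Carlo Hardy-Weinberg p-values carry simulation error `~1/sqrt(n_perm)`;
  the exact enumeration used as a test oracle is only feasible for tiny
  tables.
* CLUMPY is undefined when the focal class is absent from a window; the
  pipeline's mean-imputation keeps designs comparable but discards any
  signal such cells might carry.
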