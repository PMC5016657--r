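Package: landgen
Title: Comparative Landscape Genetics with Circuit-Theory Resistance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative landscape genetics of codominant multilocus
    genotypes sampled across study cells on a heterogeneous landscape. Reads
    GENEPOP and CSV genotype tables, applies Hardy-Weinberg and missingness
    quality gates, computes diversity (rarefied allelic richness, unbiased
    heterozygosity, F_IS) and differentiation (Weir-Cockerham F_ST, Jost's D)
    with permutation p-values and bootstrap confidence intervals, tests
    isolation-by-distance and barrier hypotheses with Mantel and partial
    Mantel tests, individual-level Rousset's a-hat distances and multivariate
    spatial autocorrelograms. Builds categorical land-cover rasters into
    competing resistance surfaces, derives circuit-theory effective-resistance
    distances between study cells from sparse graph Laplacians, computes
    within-cell landscape pattern metrics (proportion of focal habitat, patch
    density, CLUMPY), and selects among landscape configuration and complexity
    models by multiple regression on distance matrices (MRDM) and
    distance-based redundancy analysis (dbRDA) under a bootstrap
    confidence-interval comparison rule. A synthetic-data module simulates
    landscapes and metapopulation genotypes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
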