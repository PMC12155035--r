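Package: ibdspc
Title: Spectral Components from Identity-by-Descent Sharing Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts pairwise identity-by-descent (IBD) segment sharing into a
    thresholded relatedness graph and extracts spectral components (SPCs) --
    eigenvectors of the graph's symmetrically normalized Laplacian -- as
    continuous covariates for recent, fine-scale population structure.
    Includes a deme-grid coalescent simulation backend (via msprime/tskit
    through the system Python) with true-IBD extraction, three phenotype
    generators (environmental smooth, environmental sharp, polygenic), and an
    evaluation suite: genotype PCA, covariate-adjusted linear GWAS, genomic
    inflation with bootstrap confidence intervals, proportion of variance
    explained, coordinate prediction R-squared, Moran's I spatial
    autocorrelation, causal-stratified p-value comparison, and Haseman-Elston
    heritability regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    data.table,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0) and tskit, on PATH,
    for the simulation module only.
Config/testthat/edition: 3
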