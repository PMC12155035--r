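# ibdspc — spectral components from IBD-sharing graphs

Population structure left over from *recent* demography — the last few
hundred generations — confounds GWAS and heritability analyses in ways that
genotype principal components (PCs) correct poorly: PCs are linear summaries
of common-variant covariance and blur the discrete, localized structure that
long identity-by-descent (IBD) haplotypes reveal. `ibdspc` implements
**spectral components (SPCs)**: continuous per-sample covariates obtained by

1. aggregating pairwise IBD sharing (total cM per pair of individuals),
2. thresholding it into an undirected relatedness graph (edge when the
   aggregate strictly exceeds 6 cM),
3. forming the graph's symmetrically normalized Laplacian
   `L_sym = I − D^{+1/2} A D^{+1/2}` (with `D^+` the Moore–Penrose inverse
   of the degree matrix), and
4. taking the eigenvectors of its smallest eigenvalues.

SPCs drop into any pipeline that consumes PLINK-style `.eigenvec` covariate
files. The package is aimed at statistical geneticists who have IBD segment
calls (e.g. iLASH output) or want to study structure correction in
simulation: it bundles a deme-grid coalescent generator (msprime/tskit via
the system Python), three phenotype models (environmental smooth,
environmental sharp, polygenic), and the standard evaluation statistics —
genotype PCA, covariate-adjusted linear GWAS, genomic inflation
`λ = median(χ²)/0.455` with bootstrap CIs, proportion of variance explained,
coordinate-prediction R², Moran's I, causal-stratified p-value comparisons,
and Haseman–Elston heritability regression.

## Worked example

From a segment file to covariates:

```r
library(ibdspc)

f <- tempfile()
writeLines(c("S1\tS2\t1\t1000000\t9000000\t7.2",
             "S1\tS3\t2\t1000000\t9000000\t8.0",
             "S2\tS3\t3\t1000000\t9000000\t6.5",
             "S1\tS4\t1\t1000000\t9000000\t1.0"), f)

seg   <- read_ibd_segments(f, "generic6")
graph <- build_graph(aggregate_pairwise(seg), threshold_cM = 6,
                     samples = c("S1", "S2", "S3", "S4"))
graph_summary(graph)
#> # A tibble: 1 × 9
#>   n_vertices n_edges n_components n_isolated ...
#> 1          4       3            2          1

basis <- compute_spcs(build_laplacian(to_adjacency(graph)), k = 3)
basis$eigenvalues
#> [1] 0.0  1.0  1.5
write_components(basis, "spcs.eigenvec", "SPC")
```

S1–S2–S3 form a triangle above the 6 cM threshold (its normalized-Laplacian
spectrum is `{0, 3/2, 3/2}`); S4 shares only 1 cM, stays isolated, and
contributes the eigenvalue-1 pair required by the Moore–Penrose convention —
so the reported low spectrum is `{0, 1, 1.5}` and every sample, isolated or
not, gets covariate values.

The same end-to-end, in one call: `spcs_from_ibd(f, "generic6", 6, k = 3)`.

A full simulation study (minutes on one CPU):

```r
sim   <- simulate_grid(grid_preset("small4x4", seed = 1))  # 16 demes, 1600 diploids, 50 Mb
ibd   <- extract_true_ibd(sim, min_cM = 3)
graph <- build_graph(aggregate_pairwise(ibd), 6, samples = sim$labels$sample_id)
spc   <- compute_spcs(build_laplacian(to_adjacency(graph)), k = 25, seed = 1)

g_common <- filter_by_frequency(sim$genotypes, maf_gt = 0.01)
pc       <- genotype_pca(g_common, k = 25)
smooth   <- simulate_smooth(sim$labels, sigma = 1, seed = 1)  # North-South gradient

coordinate_r2(spc, sim$labels, k = 8)    # r2_vertical 0.580, r2_horizontal 0.579
coordinate_r2(pc,  sim$labels, k = 25)   # r2_vertical 0.424, r2_horizontal 0.438

genomic_inflation(gwas_linear(g_common, smooth, spc, k = 25))$lambda  # 1.072
genomic_inflation(gwas_linear(g_common, smooth, pc,  k = 25))$lambda  # 1.147
```

Reading: 8 SPCs predict the deme of origin better than 25 PCs, and the
purely environmental North–South phenotype shows materially less test-
statistic inflation when adjusted with SPCs (1.07) than with PCs (1.15) —
the same qualitative picture grows much starker as more genome feeds the
graph (with a larger 5×5, 5,000-sample cohort the 8-SPC coordinate R² rises
to ~0.79). `autoplot(spc, labels = sim$labels)` shows the deme separation;
`plot_gwas_qq(list(SPC = ..., PC = ...))` overlays the QQ curves.

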