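# coexmod

Automated gene co-expression module discovery and enrichment analysis for
transcriptomic data (bulk microarray or RNA-seq), for researchers who want
modules, their functions, and their phenotype associations from a single
expression matrix without hand-tuning network parameters.

Co-expression analysis groups genes whose expression covaries across
samples into modules, the working units of transcriptional programs. The
standard weighted-network workflow has two chronic manual steps —
deciding which genes to analyze and picking the soft-thresholding power —
and `coexmod` automates both:

* **Gene selection.** Per-gene variances are modelled as an inverse-gamma
  distribution fitted by maximum likelihood; genes with improbably high
  variance (upper-tail *p* < 0.1 by default) are kept, after removing the
  25% lowest-mean genes. For count data, a negative-binomial
  variance-stabilizing transformation `x ↦ (2/√α)·asinh(√(αx))` (with a
  single dispersion α estimated from the quadratic mean–variance trend)
  removes the mean–variance dependence first.
* **Soft-threshold selection.** Correlations are powered into an adjacency
  `a = |r|^β` (unsigned) or `a = ((1+r)/2)^β` (signed). For each grid β
  the scale-free fit R²(β) — the signed log–log regression of the degree
  histogram — is computed, and the chosen β is the smallest one with
  R²(β) > τ whose *suffix* of R² values varies by less than ε: the curve
  must have stabilized, not merely crossed the threshold (τ = 0.8,
  ε = 0.1 by default). The statistic φ — area under the β × R² curve over
  the enclosing rectangle — summarizes curve stability.

Modules are then detected by average-linkage clustering of the
topological overlap dissimilarity `1 − TOM` with an adaptive,
silhouette-scored tree cut and margin-gated refinement; genes in no module
are labeled `Uncorrelated`. Given the optional inputs, modules are
characterized by hypergeometric over-representation analysis (ORA, BH
adjusted within module), preranked permutation GSEA of module activity per
phenotype class (z-score rankings, NES, BH adjusted), and per-module
interaction subnetworks with origin-flagged nodes and top-10 hubs. All
results are written as deterministic TSV/GMT/JSON tables plus a static
HTML report.

See `vignettes/coexpression-methods.Rmd` for the full methods account.

## Worked example

Simulate a two-class study with five planted modules (50 genes each, 250
uncorrelated background genes, 20 samples per class, module M1 shifted +1
sd in the "disease" class) and run the full pipeline:

```r
library(coexmod)

sim <- simulate_modular_expression(
  n_modules = 5, genes_per_module = 50, n_background_genes = 250,
  samples_per_class = c(control = 20, disease = 20),
  class_shifts = matrix(c(0, 1), 1, 2,
                        dimnames = list("M1", c("control", "disease"))),
  seed = 1)
sets <- split(names(sim$truth)[sim$truth != "Uncorrelated"],
              sim$truth[sim$truth != "Uncorrelated"])
names(sets) <- paste0("PLANTED_", names(sets))

res <- run_pipeline(sim$expr, annotation = sim$annotation, gene_sets = sets,
                    filter_pval = 0.9, low_mean_fraction = 0,
                    n_perm = 1000, seed = 3, report = FALSE)
res
#> Co-expression module analysis
#>   genes: 500 input, 451 after filtering; samples: 40
#>   soft-threshold beta = 20 (R2 = 0.811, phi = 0.554)
#>   modules: 5 named, 237 genes uncorrelated
#>   combined enrichment score: 8.825e-58
```

451 genes pass the (deliberately permissive, since this fixture has no
mean structure) variance filter; the stabilization rule settles on β = 20
with a scale-free fit of 0.811, and all five planted modules are
recovered, with the background left out. The combined enrichment score
near zero says every module matched its planted gene set essentially
perfectly in the ORA. The planted class activity shows up in the GSEA
table with the planted sign — M1 induced in "disease", mirrored in
"control":

```r
head(res$gsea[order(res$gsea$p_adjust), ], 4)
#>    module   class    es   nes       p p_adjust
#> 1      M1 control -0.77 -2.97 0.00138  0.00366
#> 5      M5 control -0.79 -2.73 0.00141  0.00366
#> 6      M1 disease  0.77  3.06 0.00140  0.00366
#> 10     M5 disease  0.79  2.77 0.00146  0.00366
```

(M5 drifts with a chance factor–class correlation at this seed; its |NES|
is smaller.) Intramodular hubs per module:

```r
head(res$hubs[res$hubs$module == "M1", ], 3)
#>   module rank      gene connectivity
#> 1     M1    1 MOD1_G008         1.40
#> 2     M1    2 MOD1_G050         1.31
#> 3     M1    3 MOD1_G040         1.12
```

Passing `out_dir = "my_run"` additionally writes the assignment TSV,
modules GMT, β-curve, filter, ORA/GSEA/hub tables, a JSON summary with all
parameters and the seed, a manifest, and `report.html` with the β curve,
module profile plots, ORA bars (reference line at adjusted p = 0.01), a
module × class NES heatmap and per-module network drawings.

A thin command-line wrapper with the same flags lives at
`inst/scripts/coexmod-cli.R` (`run` and `simulate` subcommands).

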