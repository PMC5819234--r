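---
title: "Methods: automated gene co-expression module analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated gene co-expression module analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`coexmod` automates the discovery of gene co-expression modules from a
single genes-by-samples expression matrix and their functional
characterization. The pipeline is: optional variance-stabilizing
transformation for count data, unsupervised gene selection by an
inverse-gamma model of gene variances, automatic soft-threshold selection
for a scale-free weighted network, topological-overlap clustering with an
adaptive tree cut, and then — as optional inputs allow — hypergeometric
over-representation analysis (ORA), preranked gene set enrichment analysis
(GSEA) across phenotype classes, and per-module interaction subnetworks
with hub annotation. Every stage can also be run standalone.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic fixtures do and do not establish.

# Gene selection

## Variance model

Co-expression analysis should not be run on all genes: most genes vary
only at the measurement-noise level and dilute the correlation structure.
Filtering must be unsupervised — selecting genes by differential expression
between known groups would bias the network and invalidate the scale-free
topology assumption downstream. `filter_genes()` therefore models the
per-gene sample variances $s_g^2$ as draws from an inverse-gamma
distribution, a standard conjugate model for variances, and keeps genes
whose variance is improbably *high* under the fitted distribution:

$$p_g = P(V \ge s_g^2), \qquad V \sim \mathrm{InvGamma}(\hat\alpha, \hat\beta),$$

selecting genes with $p_g <$ `filter_pval` (default 0.1). Before the fit,
the `low_mean_fraction` (default 0.25) of genes with lowest mean
expression is removed as noise.

The fit is by maximum likelihood, computed exactly through the reciprocal
transformation: if $V \sim \mathrm{InvGamma}(a, b)$ then
$1/V \sim \mathrm{Gamma}(a, \mathrm{rate}=b)$, so the gamma
profile-likelihood equation
$\log a - \psi(a) = \log \bar{y} - \overline{\log y}$ (with $y = 1/s^2$)
is solved by bisection. When that equation has no root (essentially
degenerate samples) the fit falls back to moment matching, with a message.
Zero-variance genes are excluded from the fit and never selected; their
correlations are undefined. A matrix whose variances are all equal is
rejected outright ("variance distribution degenerate").

Because the upper-tail probability is monotone decreasing in the variance,
the selected set at a smaller `filter_pval` is always nested inside the
selected set at a larger one, and rescaling the whole matrix by a positive
constant leaves the ranking unchanged — both properties are tested.

## Variance-stabilizing transformation

For count-like data (RNA-seq), variance grows with the mean, so a raw
variance filter simply keeps the most highly expressed genes. Under a
negative-binomial model with common dispersion $\alpha$,
$\mathrm{Var} = \mu + \alpha\mu^2$, the closed-form transformation

$$x \mapsto \frac{2}{\sqrt{\alpha}}\,\mathrm{asinh}\sqrt{\alpha x}$$

renders the variance approximately constant in the mean (the delta method
gives post-transform variance $\approx 1$), reducing to $2\sqrt{x}$ as
$\alpha \to 0$ (the Poisson case). `estimate_dispersion()` obtains a single
$\alpha$ by least squares of $(s_g^2 - \bar{x}_g)$ on $\bar{x}_g^2$ across
genes, clamped at zero. A per-gene dispersion was rejected: at the sample
sizes this pipeline targets (tens of samples) per-gene estimates are far
too unstable, and the transformation only needs the trend. The test suite
verifies that the estimator recovers a known $\alpha = 0.2$ and that the
ratio of post-transform variances between the extreme mean deciles falls
in $[0.5, 2]$ where it exceeded $5$ before the transform.

# Network construction and soft-threshold selection

Pairwise gene correlations $r_{ij}$ (Pearson by default, Spearman
available) are converted to a weighted adjacency with the soft threshold
$\beta$: unsigned networks use $a_{ij} = |r_{ij}|^\beta$ and signed
networks first rescale into $[0,1]$, $a_{ij} = ((1+r_{ij})/2)^\beta$. The
base correlation matrix is computed once and powered per $\beta$, which is
both exact and fast. The diagonal is stored as 1 but excluded from every
connectivity sum.

## Scale-free fit

A biologically plausible co-expression network has an approximately
power-law degree distribution. `scale_free_fit()` bins the connectivities
$k_i = \sum_{j \ne i} a_{ij}$ into 10 equal-width bins, drops empty bins
(no pseudo-counts), and regresses $\log_{10}$ frequency on $\log_{10}$
mean connectivity. The reported index is the *signed* fit
$R^2 = -\mathrm{sign}(\mathrm{slope}) \cdot R^2_{\mathrm{lm}}$, so that an
*increasing* degree distribution — anti-power-law — cannot score well.
Degenerate histograms (all connectivities equal, or constant bin
frequencies) yield $R^2 = 0$ with a warning rather than an error.

## Choosing beta: the stabilization rule

The classic rule takes the smallest $\beta$ with $R^2(\beta) > \tau$. Its
failure mode is a curve still climbing steeply at that point: the chosen
$\beta$ then sacrifices substantial scale-freeness that one more step
would have captured. `select_beta()` instead demands that the curve has
*stabilized*: it returns the smallest grid $\beta_i$ such that
$R^2(\beta_i) > \tau$ **and** all pairwise differences of
$\{R^2(\beta_j)\}_{j \ge i}$ are below $\varepsilon$ — i.e. the suffix of
the curve varies less than $\varepsilon$. This stabilization demand is
what lets $\tau$ default to 0.8 rather than a more conservative 0.85.
With $\varepsilon = \infty$ the rule reduces exactly to the classic one
(a tested invariant). Defaults: grid $1..20$, $\tau = 0.8$,
$\varepsilon = 0.1$, full-suffix window (a fixed-length window is
configurable; the full suffix is the stricter and simpler choice).

When no $\beta$ qualifies the function returns `NA` with a per-candidate
diagnostic of suffix spreads; the pipeline then aborts unless a
`force_beta` fallback was supplied (the forced value is logged loudly).

## The phi statistic

$\varphi$ summarizes the whole curve: the trapezoidal area under
$\max(R^2, 0)$ over the grid, divided by the area of the enclosing
rectangle (grid span $\times$ 1). $\varphi$ near 1 means the topology
converges sharply to scale-free; low $\varphi$ flags unstable curves,
typically from too few samples (empirically, curves stabilize around 20
samples). Negative fit values are clamped at zero so $\varphi \in [0,1]$.

## Topological overlap

Direct adjacency is noisy; two genes belong together when they also share
neighbors. The topological overlap matrix is

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
 \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

with unit diagonal. The implementation is a matrix product with the
diagonal zeroed, checked against a brute-force triple loop to $10^{-12}$.

# Module detection

Genes are clustered by average-linkage hierarchical clustering on
$1 - \mathrm{TOM}$. The cut is the part of the procedure with the most
genuine design freedom, and two earlier candidates were rejected on the
package's own synthetic fixtures before settling on the shipped rule:

1. **Silhouette-scored adaptive cut.** Every distinct merge height is a
   candidate (downsampled to ≤ 120 for large trees). A candidate partition
   is scored by the summed silhouette width
   $\sum (b_i - a_i)/\max(a_i, b_i)$ over genes inside clusters of at
   least `min_module_size` (default 20) members, where $a_i$ is the mean
   dissimilarity to the own cluster and $b_i$ to everything else. The
   best-scoring height wins. Simply maximizing the *number* of qualifying
   clusters was rejected: near the top of the tree, agglomerates of
   uncorrelated genes inflate the count while module purity collapses.
   Weighting counts by the height range over which they persist was also
   rejected: small counts trivially persist the longest.
2. **Margin-gated refinement.** Genes outside qualifying clusters start as
   "Uncorrelated". Define a gene's *margin* for a module as its mean
   dissimilarity to the rest of the network minus its mean dissimilarity
   to the module's members. Iteratively, members whose margin falls below
   `margin_frac` (default 0.25) of the module's median member margin are
   demoted, and unlabeled genes whose margin clears the same threshold
   join their nearest module, until a fixed point (≤ 20 iterations). The
   gate is self-calibrating: genuinely uncorrelated genes are roughly
   equidistant from everything, so their margins sit near zero at any
   dissimilarity scale — important because at large $\beta$ all TOM
   dissimilarities compress toward 1 and any absolute threshold fails. A
   simple "closer to the module than to the rest" rule without the gate
   absorbed the majority of planted background genes and was rejected.
   Modules that shrink below `min_module_size` are dissolved.

Labels are `M1..Mk` by decreasing size, plus the reserved label
`Uncorrelated`; unassigned genes are kept in all outputs but excluded from
ORA, GSEA and hub ranking. On planted factor-model fixtures (5 modules of
50 genes, loading 0.9, noise sd 0.5, 250 background genes, 40 samples) the
procedure recovers the planted partition with adjusted Rand index ≥ 0.9
across seeds and leaves the background out; zero-noise blocks are
recovered exactly.

Module **eigengenes** are the unit-norm first right singular vectors of
the standardized module submatrices (one score per sample), sign-oriented
to correlate non-negatively with the module mean profile, with the
explained-variance fraction reported. Optional **merging**
(`merge_similar()`, off by default) iteratively fuses the module pair with
the highest eigengene correlation while it exceeds `merge_threshold`
(default 0.8), recomputing eigengenes after each fusion; module count
never increases and the operation is idempotent at the fixed point.
**Hubs** are the `top_n` (default 10) genes per module by intramodular
connectivity — the summed adjacency to the other members — with
alphabetical tie-breaks.

# Enrichment analyses

## Over-representation (ORA)

Per (module, gene set): the upper-tail hypergeometric probability of
drawing at least the observed overlap when $|$module$|$ genes are drawn
from the filtered-gene universe. Gene sets are intersected with the
universe first. P-values are Benjamini–Hochberg adjusted *within each
module across its sets* — the quantity shown in per-module enrichment bar
plots; a global adjustment would mix modules of very different sizes. The
implementation is `stats::phyper` and is checked against exhaustive
combinatorial enumeration on every configuration with universe ≤ 30.

The **combined enrichment score** condenses a run into one number: the
geometric mean, across named modules, of each module's minimum adjusted
ORA p-value (1 for a module with no rows). It is 1 exactly when nothing is
enriched and strictly decreases whenever any module's best p-value
improves. The geometric-mean form is this package's own construction,
chosen for that monotonicity; it is an approximate summary, not a
calibrated statistic.

## Class-ranked GSEA

With a sample annotation, each gene is z-scored across **all** samples and
each phenotype class receives per-gene scores: the mean z over the class's
samples. Genes sorted by decreasing score form the class ranking. Since
z-scores sum to zero across samples, the class-size-weighted mean of each
gene's class scores is zero: a module induced in one class is necessarily
repressed in the rest, which is exactly the contrast wanted.

Each detected module is then tested as a gene set against each class
ranking with the weighted Kolmogorov–Smirnov statistic (hit increments
proportional to $|score|$, weight exponent 1; miss increments
$1/(N - N_{hit})$; ES is the running sum's maximum deviation). The null
distribution is gene-label permutation: `n_perm` (default 1000) random
same-size gene sets under an explicit, mandatory seed. A sample-label null
was rejected because the class designs here are routinely tiny (a handful
of samples per class). The nominal p is the fraction of same-sign permuted
ES at least as extreme, with the standard $+1$ continuity correction so
permutation p-values are never zero; NES is the ES divided by the mean
|same-sign permuted ES|. BH adjustment is applied globally across
(module, class) pairs. The ES implementation agrees with a brute-force
running-sum oracle and with `fgsea::calcGseaStat` to $10^{-8}$; permutation
p-values are bit-for-bit reproducible under a fixed seed.

Reports mark adjusted p < 0.01 as the significance reference line.

# Interaction subnetworks

Given an optional undirected gene–gene interaction list, each module's
graph keeps the edges touching at least one member; non-member endpoints
are retained and flagged `interaction_added` (module members are
`module`), matching the blue/red origin coloring convention of module
network displays. One-hop expansion only — deeper expansion is not implied
by that display and was rejected. Node degree within this graph determines
the ≤ 10 labeled display hubs; this degree is deliberately distinct from
the adjacency-based intramodular connectivity of `hub_genes()`, and both
are reported under different names.

# Synthetic data

The generators in this package are first-class, tested code; they define
the conditions under which the pipeline's statistical behavior is
verified.

* `simulate_modular_expression()`: a single-factor model per module —
  member gene $= \lambda f_m + \sigma \epsilon$, background genes pure
  noise, per-class activity shifts added to the factors. The expected
  within-module correlation is $\lambda^2 / (\lambda^2 + \sigma^2)$
  (0.764 at the default $\lambda = 0.9$, $\sigma = 0.5$), which makes
  adjacency, TOM and eigengene behavior checkable in closed form, and the
  class shifts give GSEA a planted direction. Defaults (5 modules × 50
  genes, 250 background genes, 20 samples per class) mirror a small
  two-group transcriptomic study.
* `simulate_nb_counts()`: negative-binomial counts with
  $\mathrm{Var} = \mu + \alpha\mu^2$, gene means log-uniform over
  `mean_range` (default 5–5000, spanning typical RNA-seq expression).
* `simulate_interactions()`: Bernoulli edges, `within_p` inside modules,
  `between_p` elsewhere.

All generators are pure functions of their configuration and a mandatory
seed.

**What passing these fixtures does not show.** The factor model has
Gaussian noise, no batch effects, no correlated background, no
heavy-tailed microarray noise, and exactly one factor per module; real
modules overlap, nest, and drift across conditions. Recovery of planted
single-factor modules is a necessary sanity property, not evidence about
any particular real dataset.

# Numerical and degenerate-input choices

* Missing/non-numeric expression values are a parse error naming the cell
  — never imputed, since imputation silently changes correlations.
  Duplicate gene rows collapse to the highest-mean row (the usual
  probe-collapse convention), logged.
* Zero-noise (perfectly correlated) modules make the degree histogram
  degenerate, so the fit curve carries no information and `select_beta`
  returns `NA`; any sufficiently large $\beta$ is equivalent there, and
  the tests use the grid midpoint through the `force_beta` mechanism.
* Dissimilarity/connectivity ties break deterministically (lowest gene
  index or alphabetical order), and all randomness flows through explicit
  seeds, so identical inputs give byte-identical outputs.
* Problem sizes in the test suite (hundreds of genes, tens of samples,
  universes ≤ 30 for the exact ORA enumeration, 500–1000 permutations)
  were chosen so closed-form and brute-force oracles stay exact while the
  full suite runs in well under a minute per file.

# Known limitations

* The adaptive cut is a deliberately simple stand-in for the full dynamic
  tree cut family; it has no deep-split control and no nested-module
  awareness. Its planted-module recovery is tested; agreement with any
  specific dynamic-tree-cut configuration is not claimed.
* The common-dispersion VST under-corrects genes whose dispersion deviates
  strongly from the global trend.
* The combined enrichment score is an uncalibrated summary; compare runs
  with it, do not interpret it as a probability.
* ORA/GSEA treat gene identifiers as opaque strings; no identifier
  mapping, no topology-aware enrichment.
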