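---
title: "Methods: diversity and co-occurrence network inference for multi-domain rumen microbiota"
author: "rumennet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and co-occurrence network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumennet)
```

## The analysis problem

Rumen digesta hosts four interacting microbial domains — bacteria, archaea,
ciliate protozoa and anaerobic fungi — whose genus-level composition responds
to diet. A typical feeding trial is tiny by statistical standards: four
cannulated cows receive four diets (high or low concentrate, H/L, with or
without sunflower oil, HSO/LSO) in a 4 × 4 Latin square, giving 16 samples.
`rumennet` implements the statistical pipeline for such a study:

1. **Community description** — per-sample alpha diversity (richness, Shannon
   H with natural logs, Simpson 1−D, Pielou J = H/log S), Bray–Curtis
   dissimilarities, non-metric multidimensional scaling (NMDS), and
   one-way PERMANOVA on diet.
2. **Co-occurrence networks** — for each of three diet-change comparisons
   (L-H, L-LSO, H-HSO; 8 samples each) a sparse Gaussian graphical model is
   estimated from log-transformed counts, and the selected partial
   correlations define signed taxon networks analysed for centrality, hubs,
   within-domain edge enrichment and edge density.
3. **Synthetic ground truth** — a generator produces study-shaped count
   tables from a known sparse precision matrix, so every stage can be
   validated against planted structure.

## Data model

A `count_table` couples a taxa × samples matrix of non-negative counts with
per-taxon domain labels and per-sample metadata (cow, period, diet), plus an
*observedness mask*. The mask distinguishes "domain not assayed for this
sample" from "zero count": in the motivating design the fungal community is
unavailable for HSO samples, so fungal × HSO cells carry `mask = FALSE` and
propagate as missing values, never as zeros, into every transform. This is
what makes "pairwise complete observations" well defined downstream.

Rare taxa are removed once, on the full 16-sample table, by the conventional
rule *mean count per observed sample ≥ 2*; the boundary is retained. Applying
the filter globally (rather than per comparison) keeps one taxon universe
across all three diet-pair analyses.

Counts entering network inference are transformed as `ln(count + 1)`. The
pseudocount of 1 (zero counts map to 0) is exposed as an argument; the
procedure that motivated the package is silent on zeros, and 1 is the common
convention for absolute amplicon counts. A `log2` z-score transform
(per-taxon standardization to mean 0, sd 1, sample-sd convention) is provided
for abundance-profile analyses.

## The estimator

The core of the package is `ebic_glasso()`, a classed model fit in four
steps:

**Pairwise-complete correlation.** Pearson correlations are computed for
each pair of taxa over the samples where both are observed
(`pairwise_complete_correlation()`). Variables observed in fewer than 3
samples or with zero variance are dropped and reported. The resulting
pseudo-correlation matrix need not be positive definite — both because of
missingness patterns and because p (≈76 taxa) far exceeds n (8 samples).
The effective sample size reported for model selection is the *minimum*
pairwise complete count (conservative; a `mean` strategy is selectable).

**Nearest-PD repair.** The matrix is projected to the nearest
positive-definite correlation matrix by Higham's alternating projections
with Dykstra correction (eigenvalue clipping alternated with unit-diagonal
restoration), delegated to `Matrix::nearPD()` — the same tool the motivating
analysis used. Defaults: eigenvalue floor 1e-6 relative to the largest
eigenvalue, convergence tolerance 1e-7, at most 100 iterations (the best
iterate is returned with a flag if the limit is hit, which is routine for
rank-8 pseudo-correlations).

**Graphical lasso.** For a penalty λ the estimator maximises

    log det Θ − tr(R Θ) − λ Σ_{i≠j} |Θ_ij|

over positive-definite precision matrices Θ, with the penalty on
off-diagonals only (the diagonal is unpenalised, so λ = 0 recovers the exact
inverse and the 2 × 2 problem has the closed form: an edge exists iff
|r| > λ, with W12 = sign(r)(|r| − λ)). The solver is a blockwise coordinate
descent written for this package (C++ via RcppArmadillo): each column of the
covariance estimate W is updated by solving a lasso subproblem, warm-started
along the path; convergence is declared when the mean absolute change of W
falls below `tol ×` mean |off-diagonal of R| (`tol = 1e-4`, ≤ 200 sweeps).
Entries with |Θ_ij| < 1e-10 are treated as exact zeros when counting edges.

**EBIC selection.** The path uses 100 log-spaced penalties from
λ_max = max |off-diagonal R| down to 0.01 λ_max (both exposed). Each fit is
scored with the Extended Bayesian Information Criterion

    EBIC = −2 l + E log n + 4 E γ log p,  l = (n/2)(log det Θ − tr(R Θ)),

with E the number of edges. γ defaults to 0.5, the common conservative
default of EBIC-based graph selection; γ = 0 reduces to the BIC. The
smallest-EBIC penalty is selected, ties resolving to the larger penalty
(sparser model). The selected precision converts to partial correlations
`pcor_ij = −Θ_ij/√(Θ_ii Θ_jj)`, the edge weights of the network.

The fit prints, summarises, and supports `coef()` (the partial-correlation
matrix), `plot()` (EBIC and edge count along the path) and `simulate()`
(draws from the selected Gaussian model).

### Behaviour at the study's sample size

With n = 8 and p ≈ 76 the EBIC edge cost is log 8 + 2 log 76 ≈ 10.7 per
edge, while the largest likelihood gain a single edge of correlation r can
contribute is 8 log(1/(1−r²)) — below 10.7 for every |r| ≤ 0.86. Null
correlations at n = 8 regularly exceed 0.8, so no isolated real edge can
separate from noise and the selection is the empty graph for essentially any
attainable synthetic signal. This is the estimator being honest about eight
samples, and users should expect empty or near-empty selected models at this
size; informative networks require either far stronger collective structure
than independent noise admits or more samples (see the validation design
below).

## Network statistics

`build_network()` keeps an edge when |pcor| strictly exceeds a threshold;
following the motivating study the pipeline reports a permissive (0.05) and
a robust (0.25) network, with all analysed taxa kept as nodes.

* **Weighted betweenness** (`weighted_betweenness()`): shortest paths with
  edge length 1/|pcor| — the convention that stronger associations are
  shorter — computed by igraph, with equal splitting among tied shortest
  paths; validated in the tests against an exhaustive path-enumeration
  oracle. Z-scores standardize raw betweenness across nodes.
* **Hubs** (`identify_hubs()`): taxa with betweenness z-score above 1.5.
  The 1.5 cutoff is interpreted on the standardized scale, since raw
  betweenness has no natural 1.5; this interpretation is an assumption and
  is exposed as a parameter.
* **Vicariance test** (`vicariance_binomial_test()`): of the edges incident
  to a focal domain, the count with both endpoints inside it is compared to
  a binomial null. The null proportion is p0 = (n_d − 1)/(N − 1): given one
  endpoint in a domain with n_d of the N nodes, the chance the other
  endpoint also lies there under uniform endpoint choice. The default
  alternative is one-sided *greater* ("taxa interact more within their own
  domain"); both choices are package conventions, documented rather than
  inferred, and the exact binomial machinery is `stats::binom.test`.
* **Edge density** (`domain_edge_density()`): 100 × realized/possible node
  pairs, within one domain, within a pooled set of domains, or overall.
* **Betweenness ANOVA** (`betweenness_domain_anova()`): standard one-way F
  across domains on raw betweenness, with the degenerate all-equal case
  returned as F = 0, p = 1.

## Community statistics

Bray–Curtis dissimilarities come from `vegan::vegdist`; diversity indices
are the textbook formulas (cross-checked against vegan). Two procedures are
implemented in-package for full control of seeding and permutation logic:

* **PERMANOVA** (`permanova()`): the one-way dissimilarity-based
  decomposition SS_total = Σ_{i<j} d²_ij/N, SS_within = Σ_g Σ_{i<j∈g}
  d²_ij/n_g, pseudo-F = (SS_among/(a−1))/(SS_within/(N−a)), with
  significance from free permutation of labels and
  p = (1 + #{F_perm ≥ F_obs})/(1 + B), B = 999 by default. The
  implementation matches `vegan::adonis2` exactly on the statistic and SS
  decomposition (tested). Free permutation follows the motivating analysis;
  no cow/period strata are used. Note that with two groups the label
  permutations reproducing the observed partition tie F exactly, so the
  attainable minimum p is slightly above 1/(B+1); with three or more
  well-separated groups the floor is reached.
* **NMDS** (`nmds()`): Kruskal stress-1 minimised by alternating isotonic
  regression (primary tie treatment: tied dissimilarities may receive
  unequal disparities) with Guttman-transform configuration updates; any
  step that would increase stress terminates the start, which guarantees a
  monotone stress trace. The reported solution is the best of a metric
  (principal-coordinates) start plus `n_starts` random starts (default 10).
  No auto-transformation or tie-specific variants are applied; this is the
  simplest defensible Kruskal-1 implementation, deliberately plainer than
  the ecology toolkit's heuristics, and reaches comparable or lower stress
  on the fixtures tested.

## The synthetic generator

`generate_study()` emulates the study design: 16 samples (4 cows × 4
periods, cyclic Latin square over H/HSO/L/LSO), 78 genus-level taxa
(37 bacteria, 11 archaea, 14 protozoa, 16 fungi — the counts of
diet-evaluated taxa in the motivating study), and an optional wholly-missing
fungi × HSO block (on by default).

Dependence is planted in a latent Gaussian: `sample_sparse_precision()`
draws an Erdős–Rényi-style support with separate within- and between-domain
edge probabilities and signed weights, sets the diagonal to
max(1, rowsum/0.95) of absolute off-diagonals (strict diagonal dominance,
hence positive definiteness) and rescales to unit diagonal. Under this rule
the planted partial correlation of an edge between low-degree taxa is
approximately the drawn weight, so signal strength is directly
controllable. Latents are drawn with covariance Θ⁻¹, then rescaled to unit
marginal variance before the count step — a diagonal scaling that leaves the
planted support and partial correlations untouched while keeping the softmax
step's compositional distortion mild. Counts are multinomial per sample
(probabilities ∝ exp(latent), total = sequencing depth, default 50 000), so
column sums equal the depth exactly.

Diet effects are mean shifts on the latent log scale: by default 12 taxa
receive a ±log 2 (2-fold) shift, alternating concentrate-level effects
(applied to L and LSO) and oil effects (applied to HSO and LSO), with random
signs. Defaults for the dependence structure (within-domain edge probability
0.05, between 0.01, |weights| 0.25–0.45) produce planted partial
correlations mostly in the 0.2–0.45 range — moderate, realistic
co-occurrence signal.

What the generator does *not* emulate: sequencing-depth variation between
samples, overdispersion beyond multinomial, taxonomic mis-assignment, OTU
clustering noise, or phylogenetic correlation of effects. Passing recovery
tests on these data therefore demonstrates correctness of the estimation
machinery, not robustness to every artefact of real amplicon data.

## Validation design and problem sizes

The test-suite sizes are chosen so each property is checked where it is
informative:

* Solver correctness: 50 random positive-definite correlation matrices with
  p ∈ {2, 3, 4}, where the glasso objective is compared against a generic
  numerical optimizer (BFGS over a Cholesky parameterisation with smoothed
  |·|, polished by Nelder–Mead on the exact objective) to 1e-4, plus the
  exact 2 × 2 closed form and the λ → 0 / λ ≥ λ_max limits.
* Support recovery: 10 studies at the full taxon dimension (p = 78) with
  n = 500 latent draws; the permissive (|pcor| > 0.05) network of the
  selected model is scored against the planted support — mean precision
  0.99, and recall ≈ 1.0 of planted |pcor| ≥ 0.3 edges. The raw support
  also contains a fringe of near-zero entries (all below 0.07 in
  magnitude), which is why the thresholded network is the scored object —
  it is also the object the analysis actually uses.
* End-to-end enrichment: the full pipeline (counts → filter → transform →
  correlation → repair → EBIC-glasso → networks → vicariance) must detect
  planted within-bacteria enrichment. Because the 8-sample comparison is
  provably uninformative (see above), this is validated on
  `strong_signal_config()`: a 64-cow virtual herd (128 samples per diet
  pair) with dense, strong within-bacteria edges (probability 0.05,
  |weights| 0.85–0.92) and sparse between-domain edges (0.002). Over ten
  seeds the bacteria vicariance test at the 0.25 threshold is significant,
  and no unenriched domain is, in at least 8 of 10 runs. Byte-level
  determinism of the whole pipeline is checked at the study's actual
  4-cow size.
* PERMANOVA calibration: 500 null replicates (two groups of 8, 199
  permutations) give a rejection rate of 5% ± 2% at α = 0.05.

## Numerical choices and edge cases

* Zero-variance taxa in the z-score transform become rows of zeros with a
  warning (rather than NaN), so downstream stages see finite values.
* Correlations are clamped to [−1, 1]; pairs with fewer than two complete
  observations (possible under pathological masks) get correlation 0 with a
  warning before the PD repair.
* `glasso_fit` refuses non-PD inputs and points to the repair function; the
  λ = 0 case is computed by direct inversion (it is the exact solution).
* In the C++ core the recovered Θ_jj denominators are floored at 1e-12,
  guarding against loss of positive definiteness in W under extreme
  ill-conditioning (rank-deficient repaired matrices at small penalties).
* Glasso solution paths are not exactly support-monotone; edges of
  |pcor| ≲ 0.01 may flicker near their entry penalty. The tested guarantee
  is that no edge of material weight appears as λ grows.
* The vicariance test is undefined for a domain with no incident edges
  (reported as an error, treated as "no evidence of enrichment" by the
  pipeline report); p0 degenerates if a domain holds all or one node.
* NMDS terminates a start rather than accept a stress increase; with
  all-equal dissimilarities the metric start already has zero stress.

## Known limitations

* The estimator assumes (log-scale) Gaussianity; no copula or
  compositional-aware variants (e.g. covariance-shift corrections) are
  implemented. For compositional data the inferred edges conflate
  biological co-occurrence with closure effects — as does any
  correlation-based method on relative data.
* EBIC's effective-n with missing blocks is a convention (minimum pairwise
  count); no principled missing-data likelihood is used.
* Free permutation in PERMANOVA ignores the Latin-square structure; a
  strata-aware option would be more faithful to the repeated-measures
  design but is deliberately out of scope here.
* Eight samples per comparison cannot support network selection at γ = 0.5;
  results on real studies of this size should be read as exploratory.
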