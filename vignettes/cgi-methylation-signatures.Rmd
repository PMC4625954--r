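---
title: "Methylation signatures of CpG islands, shores and shelves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation signatures of CpG islands, shores and shelves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgimeth)
```

# The scientific problem

Promoter CpG islands (CGIs) are usually unmethylated in normal tissue, and
their aberrant hypermethylation in cancer is classically interpreted as a
silencing mechanism. The picture becomes richer when the island's flanks
are included — *shores* (up to 2 kb from the island edge) and *shelves*
(2–4 kb) — because methylation there is more variable between individuals
and more tissue-specific than in the island itself. `cgimeth` implements a
complete analysis of this interplay on matched methylation / expression /
copy-number / clinical cohorts:

1. **Shape analysis.** Per CGI+shores/shelves unit ("CGI+SS"), the mean
   methylation profile across a sample set is a curve over probe
   positions. These signatures are compared with a dynamic time warping
   (DTW) distance and Ward-clustered, yielding a small number of
   characteristic shapes: hypomethylated islands with hypermethylated
   flanks (cluster 1), fully hypermethylated units (cluster 2), and — in
   cancer only — a hemi-methylated class (cluster 3), split into "3up"
   (hypomethylated in normal tissue) and "3down" (hypermethylated in
   normal tissue).
2. **CIMP survival stratification.** The hypermethylation of 3up units is
   concentrated in a subgroup of patients (a CpG-island methylator
   phenotype). Patients are stratified low/intermediate/high by their
   mean 3up methylation and the strata are tested for prognostic value by
   Kaplan–Meier/log-rank and multivariate Cox regression.
3. **Predictive R².** Per gene, the out-of-sample variance in expression
   explained by its promoter methylation is quantified as the squared
   Pearson correlation between cross-validated predictions and held-out
   observations, under a mean-methylation least-squares model, a
   full-profile lasso/ridge, a CNV-only model, and a combined model.

Because the original cohort data are not redistributable, the package
ships a synthetic-cohort generator with recorded ground truth; every
analysis claim is tested as a *recovery* property against that truth.

# The DTW distance and its boundary conditions

A signature is the pair of vectors (positions, mean betas). Two
signatures with $m$ and $n$ probes are compared by

$$D = \min_{w} \sum_{k=1}^{K} \left( y^1_{w_1^k} - y^2_{w_2^k} \right)^2$$

over monotone warping paths $w$ whose indices each advance by 0 or 1 per
step (at least one advancing). Only the beta values enter the cost;
positions matter for axis standardization and region labels, not for the
alignment itself. Three boundary conditions are implemented:

* **partial** (the `dtw_distance()` default): the path may start on the
  first element of either signature and end on the last element of
  either. This is the open-begin/open-end form.
* **fixed**: the path runs from $(1,1)$ to $(m,n)$, covering both
  signatures completely.
* **printed**: an asymmetric open-end variant retained for comparison
  (its end set indexes both signatures by the second one's length); it
  is symmetrized by averaging when building a matrix.

**Why clustering uses the fixed variant.** The open-open path set admits
single-cell paths at the grid corners (the cell $(m,1)$ is both a valid
start and a valid end). Since every CGI+SS archetype carries
hypermethylated shelves at both extremities, any two signatures — however
different in the island — can be aligned corner-to-corner at near-zero
cost, and all pairwise distances collapse to noise level. We verified
this numerically: with open boundaries the within-class and between-class
distances of the three archetypes are indistinguishable (all $\approx
0$), while the fixed-endpoint distance separates them by two orders of
magnitude. `dissimilarity_matrix()` therefore defaults to
`boundary = "fixed"`; the open form remains available and is exactly what
`dtw_distance()` computes by default, verified against exhaustive path
enumeration in the test suite. No path-length normalization is applied by
default (the cost is the raw sum); `normalize = TRUE` divides the optimal
cost by its path length.

Ward clustering is performed on the DTW dissimilarity matrix directly
(`stats::hclust(method = "ward.D")`, the classical Lance–Williams update
without squaring — the DTW costs are already sums of squares). Because
the dendrogram cut order is arbitrary, clusters are relabelled
canonically from the mean island methylation of their members: cluster 1
is the most hypomethylated, cluster 2 the most hypermethylated, clusters
3+ the intermediates in ascending order. This keeps "cluster 3 =
hemi-methylated" stable across runs and conditions.

The number of clusters is chosen by subsampling stability: per repeat,
two independent 80% subsamples are clustered at each candidate $k$ and
compared by the Fowlkes–Mallows index on their intersection; the selected
$k$ is the largest whose mean stability over 100 repeats exceeds 0.9
(with a fallback to the most stable $k$ when none passes).

# The predictive-R² framework

For each gene with a retained ($\geq 20$ probes) CGI+SS — multi-CGI genes
resolve to the island whose midpoint is closest to the TSS — the score is
estimated by 3-fold cross-validation: per repeat, folds are drawn at
random, out-of-fold predictions are pooled, and the squared Pearson
correlation with the observations is recorded; the final score averages
100 repeats (scaled down where runtime matters; the repeat count is a
parameter everywhere). Penalized models choose their penalty on a nested
3-fold grid of 50 values log-spaced from $\lambda_{\max}$ (the smallest
penalty zeroing all lasso coefficients) down to $10^{-4}\lambda_{\max}$,
minimizing validation MSE. Predictors are standardized inside the
penalized fit, which also puts the appended CNV log-ratio column on the
same footing as the betas in the combined model. The deepest (smallest
penalty) grid points occasionally do not converge within the iteration
cap; the solver then returns the path for the larger penalties, which is
sufficient because the inner validation minimum never sits at an
unconverged extreme of the grid.

Two conventions deserve note. Constant predictions (e.g. an empty lasso
model on a null gene) have undefined correlation and contribute 0 to the
score. Negative correlations are *not* clipped before squaring — the
square is already non-negative — but anti-correlated repeats are counted
and exposed as an attribute, because silently squaring them would reward
anti-predictive models.

Gene-level copy number is the segment mean log-ratio of the SEG interval
(0-based, half-open) containing the TSS, with gaps filled from the
nearest segment within 1 Mb.

# The synthetic cohort: what it emulates, and what it does not

The generator (`sim_config()` / `simulate_cohort()`) plants exactly the
structure the analysis assumes, with defaults chosen once as a realistic
stated world:

* **Archetype shapes.** The majority curve rises sigmoidally from beta
  ≈ 0.1 in the island through hemi-methylated shores to ≈ 0.8 shelves;
  cluster 2 is flat at 0.8. Archetype fractions default to
  0.70/0.10/0.10/0.10 (cluster 1 dominates real promoter CGIs, roughly
  nine in ten, with a hypermethylated minority and a cancer-specific
  remainder).
* **CIMP structure.** Cluster-3up units keep the cluster-1 shape in
  normal samples. In cancer, island/shore methylation rises only in the
  CIMP strata: the "high" stratum (default 25% of patients) near-fully
  hypermethylates (penetrance 0.93) and the "intermediate" stratum
  (default 25%) reaches about half — so per-patient values are bimodal
  while the population mean signature is hemi-methylated, and three
  patient classes exist by construction for the survival stratification.
  Cluster-3down units partially demethylate in every cancer sample.
* **Noise.** Probe betas are Beta(mean·c, (1−mean)·c) draws with
  concentration c = 50, giving probe-level SD ≈ 0.05 at intermediate
  means and bounded support. Each (sample, CGI, region) additionally
  receives a Gaussian level shift (SD 0.12). This region-level term is
  what makes expression *predictable* from methylation: with i.i.d.
  probe noise only, there is almost no between-sample methylation signal
  to regress on; with a CGI-wide shift, every region would be equally
  informative and the region-resolved analysis could not localize
  anything. Region-level variation is the minimal structure supporting
  both analyses. The within-cluster variance of real signatures is not
  known from published summaries; these are calibration choices, not
  reproduced values.
* **Expression.** Log2-scale expression with per-gene Gaussian baselines
  (mean 8, SD 1); genes linked to 3up units are shifted down by 3 log2
  units in both conditions (lowly expressed already in normal tissue,
  independent of their methylation, and never methylation-regulated).
  Regulated genes (default 20) subtract `effect_size` (2.5) times a
  positively weighted sum of 2 effect probes concentrated in the
  strand-oriented 3' shore; Gaussian noise SD 0.5. The effect region is
  expressed in gene-oriented coordinates, so minus-strand genes plant
  their effects in the genomic 5' shore and the orientation logic is
  exercised.
* **Copy number.** Per sample, the chromosome is partitioned into
  Poisson-breakpoint segments whose log-ratios are 0 with probability
  0.6 and N(0, 0.4) otherwise, independent of the methylation truth; the
  dosage term (1 log2 expression unit per log-ratio unit) applies to all
  genes by default, with options to restrict it to a subset disjoint
  from the methylation-regulated genes (for independence experiments).
* **Survival.** Exponential times with baseline hazard 0.1/year
  multiplied by the planted stratum hazard ratios — 3.44 (intermediate)
  and 1.92 (high), the worst prognosis sitting in the *intermediate*
  (CIMP-low-like) stratum — administratively censored at 5 years.
  ER/HER2/node/age/size are drawn independently of survival, so their
  fitted hazard ratios should cover 1.

Not emulated: probe cross-reactivity, batch effects,
hydroxymethylation, read-depth-dependent expression noise, subclonality,
and any linkage between CNV breakpoints and methylation domains. A green
recovery test therefore establishes that the machinery identifies the
planted structure at realistic noise — not that real cohorts contain
that structure.

# Numerical and design choices

* **Coordinates.** Island intervals are 0-based half-open (BED
  convention); probes are point positions. The standardized axis maps
  the island to [0, 1] and flanks to signed kb from the island edge;
  minus-strand genes reflect the axis so positive flank coordinates are
  always 3' of the gene. The orientation is exposed as a flag because
  published descriptions of flank asymmetry rarely state their
  convention.
* **Missing data.** Probes missing in more than 10% of samples are
  dropped; remaining gaps are mean-imputed so all samples share one
  profile length (required by both DTW and regression). The threshold is
  a package choice.
* **Probe filter.** Profiles with fewer than 20 probes are excluded:
  below that, within-CGI+SS variation cannot be resolved.
* **Ties and determinism.** `hclust` is deterministic on distinct
  distances; medoid ties break by item id; every stochastic routine
  accepts a seed, and the pipeline derives stage seeds from one master
  seed, so a full run is byte-reproducible.
* **Degenerate inputs.** All-identical signatures make stability
  undefined (flagged, not fabricated); all-identical patients skip the
  stratification; Cox factor levels without events are flagged with CI
  (0, ∞) rather than failing; constant expression scores 0 with a flag.
* **Cox details.** Efron tie handling; the receptor design uses a
  combined (ER, HER2) factor with reference −/−, lymph node reference
  negative, stratum reference "low"; covariates are selectable.
* **Two-sample tests.** Cluster-wise expression comparisons use
  two-sided Mann–Whitney; paired score comparisons use the Wilcoxon
  signed-rank test. The choice is a package convention — published
  analyses of this kind rarely name the test.
* **3down stratification** is available (`target = "3down"` in
  `stratify_patients()`) but reported descriptively; the planted world
  gives it no patient substructure, matching its inconclusive role.

# Known limitations

* The open-boundary DTW variant is faithful to its printed definition
  but degenerate for clustering (see above); analyses relying on it
  should use the fixed variant, as the pipeline does.
* Predictive R² near 0 is noisy at small $n$ (its null scale is
  $1/(n-1)$ per repeat); null-gene summaries should always be compared
  against permutation controls, as the test suite does.
* The stability rule "largest k above threshold" can overshoot on small
  item sets where arbitrary splits of tight clusters remain stable;
  `k_normal`/`k_cancer` overrides exist for that reason.
* Gene-level CNV uses only the TSS-containing segment; genes spanning
  breakpoints are not modelled.
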