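# cgimeth

Analysis of promoter **CpG island + shores/shelves (CGI+SS) methylation**
and its interplay with gene expression, copy number and patient survival
in matched normal/cancer cohorts.

Promoter CGIs are classically hypomethylated; their flanking shores
(≤ 2 kb) and shelves (2–4 kb) carry most of the between-individual and
cancer-specific methylation variation. `cgimeth` is aimed at
computational epigenomics researchers who want to

* summarize each CGI+SS as a **methylation signature** — the curve of
  per-probe mean beta values `Y ∈ [0,1]^n` over probe positions — and
  cluster signatures by *shape* with a dynamic-time-warping distance

  `D(Y¹, Y²) = min over warping paths w of Σ_k (Y¹[w₁ᵏ] − Y²[w₂ᵏ])²`

  under Ward linkage with bootstrap stability selection of the cluster
  number. In cancer this recovers hypo- (cluster 1), hyper- (cluster 2)
  and hemi-methylated (cluster 3) shapes, with cluster 3 split into
  **3up/3down** by the matched normal-tissue class;
* stratify patients into low/intermediate/high mean 3up methylation
  (a CIMP-style phenotype) and test prognostic value by Kaplan–Meier /
  log-rank and multivariate Cox regression;
* quantify per gene the **predictive R²** — the squared Pearson
  correlation between repeated 3-fold cross-validated predictions and
  held-out expression — under a profile-mean least-squares model, a
  full-profile lasso/ridge (penalty chosen by nested CV), a CNV-only
  model (segment log-ratio at the TSS) and a combined model; and
  localize effects by strand-oriented region (N_shelf … S_shelf);
* generate fully synthetic matched cohorts
  (methylation/expression/SEG/clinical) with recorded ground truth, so
  every claim above is testable as a recovery property.

## Worked example

```r
library(cgimeth)

coh <- simulate_cohort(sim_config(n_cgi = 40, n_samples_normal = 30,
                                  n_samples_cancer = 60, seed = 42))
prof_c <- build_profiles(coh$betas_cancer, coh$manifest)  # >= 20 probes kept
prof_n <- build_profiles(coh$betas_normal, coh$manifest)

sig_c <- signatures(prof_c); sig_n <- signatures(prof_n)
cl_n <- ward_cluster(dissimilarity_matrix(sig_n), k = 2, signatures = sig_n)
cl_c <- ward_cluster(dissimilarity_matrix(sig_c), k = 3, signatures = sig_c)
sub  <- derive_cancer_subclusters(cl_n$labels, cl_c$labels)
print(sub)
#> Cancer-specific sub-clusters:
#>
#> 3down   3up  none
#>     4     5    13
#> Normal x cancer concordance:
#>       cancer
#> normal  1  2  3
#>      1 12  0  5
#>      2  0  1  4
```

Five CGI+SS are hemi-methylated in cancer but hypomethylated in normal
tissue (3up) and four the converse (3down); the remaining 13 keep their
class. Scoring expression predictability and stratifying patients:

```r
sc <- score_all_genes(prof_c, coh$expression_cancer, coh$manifest$genes,
                      models = c("ols_mean", "lasso_full"),
                      repeats = 20, seed = 5)
print(sc)
#> Predictive R2 scores for 22 genes (60 samples)
#>   r2_ols_mean        mean 0.037  max 0.105
#>   r2_lasso_full      mean 0.363  max 0.726
#>   paired Wilcoxon full vs mean: p = 0.000128

st <- stratify_patients(prof_c, sub$sublabels)
km <- km_logrank(st, coh$clinical, window_days = 1826)
print(km)
#> Kaplan-Meier estimate over 60 patients
#>   log-rank p = 8.914e-05
```

The full-profile lasso explains far more held-out expression variance
than the profile mean (the planted effects are sparse, 3' shore probes),
and the CIMP strata separate survival. `run_all(run_config(), out_dir,
seed)` chains all stages (simulate → profiles → cluster → 3up/3down →
scores ± CNV → survival) and writes every table plus a
`run_manifest.json` with parameters, seeds and output hashes;
`inst/exec/cgimeth` wraps `simulate` and `run-all` for the shell.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the default end-to-end pipeline on the synthetic cohort under
the given seed (all stage seeds derive from it) and writes the JSON
report to `--out`.
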