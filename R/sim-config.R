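#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the synthetic
#' methylation/expression/CNV/clinical cohort. Defaults encode the stylised
#' facts the analysis assumes: a large majority of CpG-island+shores/shelves
#' (CGI+SS) units with hypomethylated islands and hypermethylated shelves,
#' a minority fully hypermethylated, and two cancer-specific hemi-methylated
#' classes ("3up"/"3down"); a CIMP-like patient subgroup with coordinated
#' island hypermethylation; genes whose expression depends on a sparse set
#' of probes concentrated in one flank region; gene-dosage copy-number
#' effects; and survival hazards tied to the CIMP strata (hazard ratios
#' 3.44 and 1.92 for the intermediate and high strata versus low).
#'
#' @param n_samples_normal,n_samples_cancer Cohort sizes per condition.
#' @param n_cgi Number of simulated CGI+SS units.
#' @param probes_per_cgi_range Integer min/max of probes per CGI+SS; the
#'   default (10, 40) straddles the 20-probe analysis filter on purpose.
#' @param archetype_fractions Named proportions over
#'   `cluster1`, `cluster2`, `cluster3up`, `cluster3down`; must sum to 1.
#' @param cimp_fraction Fraction of cancer samples in the hypermethylated
#'   ("high") CIMP subgroup.
#' @param cimp_intermediate_fraction Fraction of cancer samples in the
#'   intermediate CIMP stratum (partial island hypermethylation).
#' @param beta_noise_concentration Precision of the beta-distributed probe
#'   noise: betas are drawn from Beta(mean*c, (1-mean)*c).
#' @param region_level_sd SD of the per-(sample, CGI, region) Gaussian level
#'   shift that creates inter-individual methylation variation.
#' @param n_regulated_genes Number of genes whose expression is driven by
#'   methylation.
#' @param n_effect_probes Effect probes per regulated gene (sparse within
#'   the profile).
#' @param effect_region Flank region, oriented by gene strand, holding the
#'   effect probes; one of `N_shelf`, `N_shore`, `island`, `S_shore`,
#'   `S_shelf`. `S_shore` = 3' shore, where the methylation-expression
#'   association concentrates.
#' @param effect_size Expression change (log2 units) per unit weighted beta.
#' @param expression_noise_sd SD of the Gaussian expression noise.
#' @param baseline_mean,baseline_sd Per-gene baseline expression (log2).
#' @param baseline_3up_shift Additive baseline shift for genes linked to
#'   cluster-3up CGI+SS (lowly expressed in both conditions).
#' @param cnv_effect_size Expression change per unit segment log-ratio.
#' @param cnv_gene_fraction Fraction of genes carrying the dosage effect
#'   (1 = all genes).
#' @param cnv_disjoint If `TRUE`, CNV-affected genes are sampled from the
#'   non-methylation-regulated genes only (disjoint planted effects).
#' @param hazard_ratio_intermediate,hazard_ratio_high Planted hazard ratios
#'   of the intermediate/high CIMP strata versus low.
#' @param baseline_hazard Exponential baseline hazard, events per year.
#' @param censor_years Administrative censoring window in years.
#' @param multi_cgi_fraction Fraction of genes additionally linked to a
#'   second CGI+SS (exercises the closest-TSS rule).
#' @param seed Integer master seed for the generator.
#'
#' @return An object of class `cgims_simconfig` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cgi = 20, n_samples_normal = 10, n_samples_cancer = 10)
#' cfg$archetype_fractions
#' @export
sim_config <- function(n_samples_normal = 50,
                       n_samples_cancer = 50,
                       n_cgi = 100,
                       probes_per_cgi_range = c(10L, 40L),
                       archetype_fractions = c(cluster1 = 0.70,
                                               cluster2 = 0.10,
                                               cluster3up = 0.10,
                                               cluster3down = 0.10),
                       cimp_fraction = 0.25,
                       cimp_intermediate_fraction = 0.25,
                       beta_noise_concentration = 50,
                       region_level_sd = 0.12,
                       n_regulated_genes = 20,
                       n_effect_probes = 2,
                       effect_region = "S_shore",
                       effect_size = 2.5,
                       expression_noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1,
                       baseline_3up_shift = -3,
                       cnv_effect_size = 1,
                       cnv_gene_fraction = 1,
                       cnv_disjoint = FALSE,
                       hazard_ratio_intermediate = 3.44,
                       hazard_ratio_high = 1.92,
                       baseline_hazard = 0.1,
                       censor_years = 5,
                       multi_cgi_fraction = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_samples_normal, n_samples_cancer, n_cgi)
  .assert(all(counts >= 1) && all(counts == round(counts)),
          "sample and CGI counts must be integers >= 1")
  .assert(length(probes_per_cgi_range) == 2 &&
            probes_per_cgi_range[1] >= 1 &&
            probes_per_cgi_range[1] <= probes_per_cgi_range[2],
          "probes_per_cgi_range must be (min, max) with 1 <= min <= max")
  .assert(setequal(names(archetype_fractions),
                   c("cluster1", "cluster2", "cluster3up", "cluster3down")),
          "archetype_fractions must be named over cluster1/2/3up/3down")
  .assert(abs(sum(archetype_fractions) - 1) < 1e-9,
          "archetype_fractions must sum to 1")
  .assert(all(archetype_fractions >= 0), "archetype_fractions must be >= 0")
  .assert(cimp_fraction >= 0 && cimp_fraction <= 1 &&
            cimp_intermediate_fraction >= 0 &&
            cimp_fraction + cimp_intermediate_fraction <= 1,
          "CIMP fractions must lie in [0,1] and sum to at most 1")
  .assert(beta_noise_concentration > 0,
          "beta_noise_concentration must be > 0")
  .assert(region_level_sd >= 0, "region_level_sd must be >= 0")
  .assert(effect_region %in% .REGIONS,
          paste("effect_region must be one of:", paste(.REGIONS, collapse = ", ")))
  .assert(expression_noise_sd > 0, "expression_noise_sd must be > 0")
  .assert(n_regulated_genes >= 0 && n_effect_probes >= 1,
          "n_regulated_genes must be >= 0 and n_effect_probes >= 1")
  .assert(cnv_gene_fraction >= 0 && cnv_gene_fraction <= 1,
          "cnv_gene_fraction must lie in [0,1]")
  .assert(hazard_ratio_intermediate > 0 && hazard_ratio_high > 0 &&
            baseline_hazard > 0 && censor_years > 0,
          "hazard ratios, baseline hazard and censoring window must be > 0")
  .assert(multi_cgi_fraction >= 0 && multi_cgi_fraction <= 1,
          "multi_cgi_fraction must lie in [0,1]")
  .assert(length(seed) == 1 && is.finite(seed), "seed must be a single integer")
  cfg$probes_per_cgi_range <- as.integer(probes_per_cgi_range)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cgims_simconfig")
}

#' @export
print.cgims_simconfig <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d CGI+SS, %d-%d probes each; %d normal / %d cancer samples\n",
              x$n_cgi, x$probes_per_cgi_range[1], x$probes_per_cgi_range[2],
              x$n_samples_normal, x$n_samples_cancer))
  cat(sprintf("  archetypes: %s\n",
              paste(sprintf("%s=%.2f", names(x$archetype_fractions),
                            x$archetype_fractions), collapse = " ")))
  cat(sprintf("  CIMP strata (low/intermediate/high): %.2f/%.2f/%.2f of cancer samples\n",
              1 - x$cimp_fraction - x$cimp_intermediate_fraction,
              x$cimp_intermediate_fraction, x$cimp_fraction))
  cat(sprintf("  %d regulated genes, %d effect probes in %s, effect size %.2f\n",
              x$n_regulated_genes, x$n_effect_probes, x$effect_region,
              x$effect_size))
  cat(sprintf("  planted HR intermediate=%.2f high=%.2f; seed %d\n",
              x$hazard_ratio_intermediate, x$hazard_ratio_high, x$seed))
  invisible(x)
}
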