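# End-to-end orchestration: simulate (or load) a cohort, build profiles,
# cluster signatures per condition, derive 3up/3down, score
# methylation/CNV predictive power, and run the survival analysis — with
# deterministic seeding derived from one master seed and a run manifest
# recording parameters, seeds and output hashes.

#' Pipeline run configuration
#'
#' Collects every stage parameter with desk-scale defaults. The
#' cross-validation repeat count defaults to 10 here (the per-gene
#' [predictive_r2()] default of 100 repeats is costly across all genes);
#' increase it for production-size runs.
#'
#' @param sim A [sim_config()] for the synthetic cohort stage.
#' @param min_probes Profile probe filter (default 20).
#' @param dtw_boundary DTW boundary condition for the dissimilarity matrix
#'   (default `"fixed"`, see [dissimilarity_matrix()]).
#' @param dtw_normalize Normalize DTW cost by path length (default
#'   `FALSE`).
#' @param k_normal,k_cancer Cluster numbers per condition: `"auto"`
#'   (bootstrap-selected) or an integer.
#' @param k_range Candidate k values for the bootstrap (default 2:6).
#' @param bootstrap_repeats,subsample,stability_threshold Bootstrap
#'   stability parameters (defaults 100, 0.8, 0.9).
#' @param n_medoids Medoids per cluster for condensed profiles.
#' @param cv_folds,cv_repeats Cross-validation scheme for predictive
#'   scores.
#' @param top_n Top genes for the region-correlation analysis.
#' @param with_cnv Run the CNV integration stage.
#' @param window_years Survival censoring window (default 5 years).
#' @param stages Named logical list enabling stages: `simulate`,
#'   `cluster`, `associate`, `cnv`, `survival`.
#' @return Object of class `cgims_runconfig`.
#' @export
run_config <- function(sim = sim_config(n_cgi = 60),
                       min_probes = 20,
                       dtw_boundary = "fixed",
                       dtw_normalize = FALSE,
                       k_normal = "auto",
                       k_cancer = "auto",
                       k_range = 2:6,
                       bootstrap_repeats = 100,
                       subsample = 0.8,
                       stability_threshold = 0.9,
                       n_medoids = 10,
                       cv_folds = 3,
                       cv_repeats = 10,
                       top_n = 50,
                       with_cnv = TRUE,
                       window_years = 5,
                       stages = list(simulate = TRUE, cluster = TRUE,
                                     associate = TRUE, cnv = TRUE,
                                     survival = TRUE)) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "cgims_simconfig"))
  defaults <- list(simulate = TRUE, cluster = TRUE, associate = TRUE,
                   cnv = TRUE, survival = TRUE)
  defaults[names(stages)] <- stages
  cfg$stages <- defaults
  structure(cfg, class = "cgims_runconfig")
}

.pick_k <- function(policy, stability) {
  if (is.numeric(policy)) return(as.integer(policy))
  k <- stability$selected_k
  if (is.na(k)) # no k passed the threshold: fall back to the most stable
    k <- stability$scores$k[which.max(stability$scores$stability)]
  k
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> build-profiles -> cluster (per condition) ->
#' derive 3up/3down sub-clusters -> predictive scoring (with CNV
#' integration) -> survival analysis, writing each stage's tables under
#' `out_dir` and a `run_manifest.json` recording parameters, derived
#' seeds and the MD5 hash of every output. Every stochastic stage derives
#' its seed deterministically from `seed`, so two runs with the same
#' configuration and seed produce byte-identical outputs.
#'
#' Disabled stages must have been run before (their outputs are read back
#' from `out_dir`); a stage whose inputs are missing aborts with the stage
#' and file name.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return The run manifest (named list), invisibly.
#' @export
run_all <- function(config = run_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "cgims_runconfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  notes <- list()
  reg <- function(path) outputs <<- c(outputs, path)
  stages <- config$stages

  # --- simulate ---------------------------------------------------------
  cohort_dir <- file.path(out_dir, "cohort")
  if (isTRUE(stages$simulate)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- as.integer(seed)
    cohort <- simulate_cohort(sim_cfg)
    write_cohort(cohort, cohort_dir)
    for (f in list.files(cohort_dir, full.names = TRUE)) reg(f)
  } else {
    if (!file.exists(file.path(cohort_dir, "manifest.tsv")))
      stop("stage 'simulate' is disabled and its outputs are missing: ",
           file.path(cohort_dir, "manifest.tsv"))
    cohort <- read_cohort(cohort_dir)
  }
  annotation <- cohort$manifest$genes

  # --- profiles ---------------------------------------------------------
  prof_n <- build_profiles(cohort$betas_normal, cohort$manifest,
                           min_probes = config$min_probes)
  prof_c <- build_profiles(cohort$betas_cancer, cohort$manifest,
                           min_probes = config$min_probes)
  retained <- data.frame(cgi_id = names(prof_c),
                         n_probes = vapply(prof_c, function(p) nrow(p$probes),
                                           integer(1)))
  .write_tsv(retained, file.path(out_dir, "retained_cgi.tsv"))
  reg(file.path(out_dir, "retained_cgi.tsv"))

  labels_n <- labels_c <- sub <- NULL
  scores_n <- scores_c <- NULL

  # --- cluster ----------------------------------------------------------
  if (isTRUE(stages$cluster)) {
    for (cond in c("normal", "cancer")) {
      prof <- if (cond == "normal") prof_n else prof_c
      sigs <- signatures(prof, condition = cond)
      D <- dissimilarity_matrix(sigs, boundary = config$dtw_boundary,
                                normalize = config$dtw_normalize)
      stab <- bootstrap_stability(D, k_range = config$k_range,
                                  n_repeats = config$bootstrap_repeats,
                                  subsample = config$subsample,
                                  threshold = config$stability_threshold,
                                  seed = .sub_seed(seed, if (cond == "normal") 11 else 12))
      k <- .pick_k(config[[paste0("k_", cond)]], stab)
      cl <- ward_cluster(D, k, signatures = sigs)
      if (cond == "normal") labels_n <- cl$labels else labels_c <- cl$labels
      .write_matrix_tsv(D, file.path(out_dir, paste0("dissimilarity_", cond, ".tsv")),
                        "cgi_id")
      .write_tsv(stab$scores, file.path(out_dir, paste0("stability_", cond, ".tsv")))
      .write_tsv(data.frame(cgi_id = names(cl$labels), cluster = cl$labels),
                 file.path(out_dir, paste0("labels_", cond, ".tsv")))
      cp <- condensed_profiles(prof, cl, D, n_medoids = config$n_medoids)
      .write_tsv(cp, file.path(out_dir, paste0("condensed_profiles_", cond, ".tsv")))
      for (f in paste0(c("dissimilarity_", "stability_", "labels_",
                         "condensed_profiles_"), cond, ".tsv"))
        reg(file.path(out_dir, f))
      notes[[paste0("k_", cond)]] <- k
    }
    sub <- derive_cancer_subclusters(labels_n, labels_c)
    .write_tsv(data.frame(cgi_id = names(sub$sublabels),
                          sublabel = sub$sublabels),
               file.path(out_dir, "sublabels.tsv"))
    .write_tsv(as.data.frame(sub$concordance),
               file.path(out_dir, "concordance.tsv"))
    reg(file.path(out_dir, "sublabels.tsv"))
    reg(file.path(out_dir, "concordance.tsv"))
  }

  # --- associate --------------------------------------------------------
  if (isTRUE(stages$associate)) {
    scores_n <- score_all_genes(prof_n, cohort$expression_normal, annotation,
                                models = c("ols_mean", "lasso_full"),
                                folds = config$cv_folds,
                                repeats = config$cv_repeats,
                                seed = .sub_seed(seed, 21),
                                condition = "normal")
    scores_c <- score_all_genes(prof_c, cohort$expression_cancer, annotation,
                                models = c("ols_mean", "lasso_full"),
                                folds = config$cv_folds,
                                repeats = config$cv_repeats,
                                seed = .sub_seed(seed, 22),
                                condition = "cancer")
    .write_tsv(as.data.frame(scores_n), file.path(out_dir, "scores_normal.tsv"))
    .write_tsv(as.data.frame(scores_c), file.path(out_dir, "scores_cancer.tsv"))
    rc <- region_correlations(scores_c, prof_c, cohort$expression_cancer,
                              annotation, top_n = config$top_n)
    .write_tsv(rc$summary, file.path(out_dir, "region_correlations.tsv"))
    conc <- cross_condition_concordance(scores_n, scores_c)
    jsonlite::write_json(list(r_squared = conc$r_squared, n = conc$n),
                         file.path(out_dir, "concordance_normal_cancer.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in c("scores_normal.tsv", "scores_cancer.tsv",
                "region_correlations.tsv", "concordance_normal_cancer.json"))
      reg(file.path(out_dir, f))
  }

  # --- cnv --------------------------------------------------------------
  if (isTRUE(stages$cnv)) {
    if (!isTRUE(stages$associate) || is.null(scores_c))
      stop("stage 'cnv' requires the outputs of disabled stage 'associate'")
    cnvsc <- cnv_expression_scores(cohort$gene_cnv, cohort$expression_cancer,
                                   prof_c, annotation, scores = scores_c,
                                   folds = config$cv_folds,
                                   repeats = config$cv_repeats,
                                   seed = .sub_seed(seed, 23))
    .write_tsv(cnvsc$scores, file.path(out_dir, "scores_cancer_cnv.tsv"))
    jsonlite::write_json(
      list(independence_r2 = cnvsc$independence_r2,
           wilcox_combined_vs_full = cnvsc$wilcox_combined_vs_full,
           wilcox_combined_vs_cnv = cnvsc$wilcox_combined_vs_cnv),
      file.path(out_dir, "cnv_independence.json"),
      auto_unbox = TRUE, digits = NA)
    reg(file.path(out_dir, "scores_cancer_cnv.tsv"))
    reg(file.path(out_dir, "cnv_independence.json"))
  }

  # --- survival ---------------------------------------------------------
  if (isTRUE(stages$survival)) {
    if (!isTRUE(stages$cluster) || is.null(sub))
      stop("stage 'survival' requires the outputs of disabled stage 'cluster'")
    window_days <- round(config$window_years * 365.25)
    if (!any(sub$sublabels == "3up")) {
      notes$survival <- "no CGI+SS labelled 3up; survival stage skipped"
    } else {
      strata <- stratify_patients(prof_c, sub$sublabels)
      km <- km_logrank(strata, cohort$clinical, window_days = window_days)
      cox <- cox_multivariate(strata, cohort$clinical,
                              window_days = window_days)
      .write_tsv(as.data.frame(strata), file.path(out_dir, "strata.tsv"))
      .write_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
      jsonlite::write_json(list(log_rank_p = km$p_value,
                                flagged = km$flagged),
                           file.path(out_dir, "logrank.json"),
                           auto_unbox = TRUE, digits = NA)
      .write_tsv(as.data.frame(cox), file.path(out_dir, "cox_summary.tsv"))
      for (f in c("strata.tsv", "km_curves.tsv", "logrank.json",
                  "cox_summary.tsv"))
        reg(file.path(out_dir, f))
    }
  }

  # --- run manifest -----------------------------------------------------
  rel <- substring(outputs, nchar(out_dir) + 2)
  hashes <- as.list(unname(tools::md5sum(outputs)))
  names(hashes) <- rel
  manifest <- list(seed = as.integer(seed),
                   parameters = .serializable_config(config),
                   stages = config$stages,
                   notes = notes,
                   outputs = hashes[order(names(hashes))])
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg
}
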