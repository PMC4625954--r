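# Relating methylation to expression: cluster-wise expression
# distributions, per-gene cross-validated predictive R-squared under
# mean-methylation / full-profile / CNV / combined models, probewise
# region-resolved correlations, cross-condition concordance of scores,
# and transcription-factor enrichment of top genes.

.R2_MODELS <- c("ols_mean", "lasso_full", "ridge_full", "ols_cnv",
                "lasso_combined")

# least-squares fit robust to collinear columns (NA coefs -> 0)
.ols_predict <- function(xtr, ytr, xte) {
  fit <- lm.fit(cbind(1, xtr), ytr)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  drop(cbind(1, xte) %*% cf)
}

# penalized fit with the nested inner CV: lambda grid of `grid_size` values
# log-spaced from lambda_max (smallest lambda zeroing all lasso
# coefficients on the training data) down to lambda_max * min_ratio;
# the inner 3-fold split picks the lambda minimizing validation MSE.
.penalized_predict <- function(xtr, ytr, xte, alpha, inner_folds,
                               grid_size = 50, min_ratio = 1e-4) {
  ntr <- nrow(xtr)
  if (sd(ytr) == 0) return(rep(ytr[1], nrow(xte)))
  sx <- apply(xtr, 2, sd)
  xs <- scale(xtr, center = TRUE, scale = ifelse(sx > 0, sx, 1))
  lmax <- max(abs(crossprod(xs, ytr - mean(ytr)))) / ntr
  if (!is.finite(lmax) || lmax <= 0) return(rep(mean(ytr), nrow(xte)))
  grid <- exp(seq(log(lmax), log(lmax * min_ratio), length.out = grid_size))
  ifold <- sample(rep_len(seq_len(inner_folds), ntr))
  mse <- numeric(grid_size)
  for (f in seq_len(inner_folds)) {
    tr <- ifold != f
    if (sd(ytr[tr]) == 0) next
    # the deepest grid points may not converge within maxit; glmnet then
    # returns the path for the larger lambdas, which is all the inner
    # MSE minimization needs
    fit <- tryCatch(
      suppressWarnings(glmnet::glmnet(xtr[tr, , drop = FALSE], ytr[tr],
                                      alpha = alpha, lambda = grid)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pv <- predict(fit, xtr[!tr, , drop = FALSE], s = grid)
    mse <- mse + colSums((pv - ytr[!tr])^2)
  }
  best <- grid[which.min(mse)]
  fit <- tryCatch(
    suppressWarnings(glmnet::glmnet(xtr, ytr, alpha = alpha, lambda = grid)),
    error = function(e) NULL)
  if (is.null(fit)) return(rep(mean(ytr), nrow(xte)))
  drop(predict(fit, xte, s = best))
}

#' Cross-validated predictive R-squared of one gene
#'
#' Measures how well a predictor matrix (probe betas, their mean, the gene
#' copy-number log-ratio, or probes+CNV combined) predicts an expression
#' vector out of sample. Per repeat, the samples are split into `folds`
#' random folds; each fold is predicted from a model fitted on the others
#' (for lasso/ridge, the penalty is chosen by a nested inner
#' cross-validation of the same fold count on a 50-value log-spaced grid
#' minimizing mean squared error); the repeat's score is the squared
#' Pearson correlation between the pooled out-of-fold predictions and the
#' observations. The final score is the mean over `repeats`. This is an
#' out-of-sample goodness of fit: unlike the training R-squared it does not
#' grow with model size, and unlike the MSE it is invariant to the scale of
#' expression.
#'
#' Undefined correlations (constant predictions, as when the inner lasso
#' selects the empty model) contribute 0. Negative correlations are *not*
#' clipped before squaring — R-squared is a square so it is already
#' non-negative — but anti-correlated repeats are counted in the
#' `n_anticorrelated` attribute, since squaring would otherwise silently
#' reward them.
#'
#' @param y Numeric expression vector (one gene across samples).
#' @param x Predictor matrix (samples x predictors) or vector.
#' @param model One of `"ols_mean"`, `"lasso_full"`, `"ridge_full"`,
#'   `"ols_cnv"`, `"lasso_combined"`. The two `ols_*` models are
#'   least-squares on the given column(s); the penalized models need at
#'   least two predictor columns (with one column they fall back to
#'   least squares, noted in the `note` attribute).
#' @param folds Outer (and inner) fold count, default 3.
#' @param repeats Number of repeated fold splits averaged, default 100.
#' @param seed Optional seed making the fold assignments reproducible.
#' @return Numeric score in `[0, 1]` with attributes `model`, `r_mean`
#'   (mean signed correlation), `n_anticorrelated`, `n_undefined` and
#'   `flag` (`"constant_response"` for a constant `y`, scored 0).
#' @export
predictive_r2 <- function(y, x, model = .R2_MODELS, folds = 3, repeats = 100,
                          seed = NULL) {
  model <- match.arg(model)
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- length(y)
  if (n != nrow(x)) stop("sample mismatch between y and x")
  .assert(n >= 12, "need at least 12 samples")
  .assert(ncol(x) >= 1, "need at least one predictor column")
  if (anyNA(y) || anyNA(x)) stop("missing values in y or x")
  if (sd(y) == 0)
    return(structure(0, model = model, r_mean = NA_real_,
                     n_anticorrelated = 0L, n_undefined = repeats,
                     flag = "constant_response"))
  penalized <- model %in% c("lasso_full", "ridge_full", "lasso_combined")
  note <- NULL
  if (penalized && ncol(x) < 2) {
    penalized <- FALSE
    note <- "single predictor: penalized model fell back to least squares"
  }
  alpha <- if (model == "ridge_full") 0 else 1
  if (!is.null(seed)) set.seed(seed)
  scores <- numeric(repeats)
  rs <- rep(NA_real_, repeats)
  n_undef <- 0L
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold == f
      xtr <- x[!te, , drop = FALSE]
      xte <- x[te, , drop = FALSE]
      pred[te] <- if (penalized)
        .penalized_predict(xtr, y[!te], xte, alpha, folds)
      else .ols_predict(xtr, y[!te], xte)
    }
    r_ <- if (sd(pred) == 0) NA_real_ else suppressWarnings(cor(pred, y))
    if (is.na(r_)) {
      n_undef <- n_undef + 1L
      scores[r] <- 0
    } else {
      rs[r] <- r_
      scores[r] <- r_^2
    }
  }
  structure(mean(scores), model = model,
            r_mean = if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE),
            n_anticorrelated = sum(rs < 0, na.rm = TRUE),
            n_undefined = n_undef, note = note, flag = NULL)
}

# gene -> profile resolution: among a gene's linked CGI+SS retained in
# `profiles`, pick the one whose island midpoint is closest to the TSS
.gene_cgi_map <- function(annotation, profiles) {
  ids <- names(profiles)
  mid <- vapply(profiles, function(p) mean(p$island), numeric(1))
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    linked <- intersect(strsplit(annotation$cgi_ids[i], ",", fixed = TRUE)[[1]], ids)
    if (length(linked) == 0) return(NULL)
    cgi <- linked[which.min(abs(mid[linked] - annotation$tss[i]))]
    data.frame(gene_id = annotation$gene_id[i], cgi_id = cgi,
               strand = annotation$strand[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score every gene's expression predictability from methylation
#'
#' Applies [predictive_r2()] to each gene with a retained (>= 20 probe)
#' CGI+SS profile, resolving genes linked to several CGI+SS to the one
#' closest to the TSS (island midpoint distance). The `ols_mean` model uses
#' the profile-wide mean beta per sample as single predictor; the
#' `*_full` models use all probes; `ols_cnv` and `lasso_combined` require
#' `gene_cnv`. When both `r2_full_model` and `r2_mean_model` are computed,
#' a paired two-sided Wilcoxon signed-rank test across genes compares them
#' (attribute `wilcoxon_full_vs_mean`).
#'
#' @param profiles A [build_profiles()] result.
#' @param expression Gene x sample expression matrix (log2 scale).
#' @param annotation Gene table (`gene_id`, `tss`, `strand`, `cgi_ids`).
#' @param models Subset of `"ols_mean"`, `"lasso_full"`, `"ridge_full"`,
#'   `"ols_cnv"`, `"lasso_combined"`.
#' @param folds,repeats Cross-validation scheme (default 3-fold, 100
#'   repeats).
#' @param seed Per-gene seeds are derived deterministically from this.
#' @param gene_cnv Optional gene x sample log-ratio matrix.
#' @param condition Optional condition tag stored on the result.
#' @return Object of class `cgims_scores`: data frame with `gene_id`,
#'   `cgi_id`, `n_probes` and one `r2_<model>` column per model.
#' @export
score_all_genes <- function(profiles, expression, annotation,
                            models = c("ols_mean", "lasso_full"),
                            folds = 3, repeats = 100, seed = NULL,
                            gene_cnv = NULL, condition = NULL) {
  models <- match.arg(models, .R2_MODELS, several.ok = TRUE)
  .assert(length(profiles) > 0, "no profiles")
  if (any(models %in% c("ols_cnv", "lasso_combined")))
    .assert(!is.null(gene_cnv), "CNV models require gene_cnv")
  map <- .gene_cgi_map(annotation, profiles)
  map <- map[map$gene_id %in% rownames(expression), , drop = FALSE]
  .assert(!is.null(map) && nrow(map) > 0, "no genes with a retained profile")
  samples <- intersect(colnames(expression), colnames(profiles[[1]]$betas))
  if (!is.null(gene_cnv)) samples <- intersect(samples, colnames(gene_cnv))
  if (length(samples) == 0) stop("no matched samples")

  out <- data.frame(gene_id = map$gene_id, cgi_id = map$cgi_id,
                    n_probes = NA_integer_, stringsAsFactors = FALSE)
  for (m in models) out[[paste0("r2_", m)]] <- NA_real_
  for (i in seq_len(nrow(map))) {
    prof <- profiles[[map$cgi_id[i]]]
    B <- t(prof$betas[, samples, drop = FALSE])
    y <- expression[map$gene_id[i], samples]
    out$n_probes[i] <- ncol(B)
    seed_i <- .sub_seed(seed, 1000 + i)
    for (m in models) {
      x <- switch(m,
        ols_mean = matrix(rowMeans(B), ncol = 1),
        lasso_full = B,
        ridge_full = B,
        ols_cnv = matrix(gene_cnv[map$gene_id[i], samples], ncol = 1),
        lasso_combined = cbind(B, cnv = gene_cnv[map$gene_id[i], samples]))
      out[[paste0("r2_", m)]][i] <-
        as.numeric(predictive_r2(y, x, model = m, folds = folds,
                                 repeats = repeats, seed = seed_i))
    }
  }
  wt <- NULL
  if (all(c("r2_lasso_full", "r2_ols_mean") %in% names(out)) && nrow(out) >= 2)
    wt <- wilcox.test(out$r2_lasso_full, out$r2_ols_mean, paired = TRUE,
                      alternative = "two.sided", exact = FALSE)
  structure(out, condition = condition, samples = samples,
            wilcoxon_full_vs_mean = wt,
            class = c("cgims_scores", "data.frame"))
}

#' @export
print.cgims_scores <- function(x, ...) {
  cat(sprintf("Predictive R2 scores for %d genes (%d samples%s)\n",
              nrow(x), length(attr(x, "samples")),
              if (!is.null(attr(x, "condition")))
                paste0(", ", attr(x, "condition")) else ""))
  for (col in grep("^r2_", names(x), value = TRUE))
    cat(sprintf("  %-18s mean %.3f  max %.3f\n", col,
                mean(x[[col]], na.rm = TRUE), max(x[[col]], na.rm = TRUE)))
  wt <- attr(x, "wilcoxon_full_vs_mean")
  if (!is.null(wt))
    cat(sprintf("  paired Wilcoxon full vs mean: p = %.3g\n", wt$p.value))
  invisible(as.data.frame(x))
}

#' Compare expression distributions across signature clusters
#'
#' Genes are grouped by the cluster (and 3up/3down sub-cluster) of their
#' associated CGI+SS; each group's values are the genes' mean expression
#' across samples, compared pairwise and against the genome-wide reference
#' set with two-sided Mann-Whitney tests. Groups with fewer than 2 genes
#' are flagged and their tests skipped.
#'
#' @param expression Gene x sample expression matrix.
#' @param clustering A [ward_cluster()] result (or named label vector).
#' @param sublabels Optional named "3up"/"3down"/"none" vector from
#'   [derive_cancer_subclusters()].
#' @param profiles The profiles clustered (for gene -> CGI resolution).
#' @param annotation Gene table.
#' @return Object of class `cgims_cluster_expression`: list with `values`
#'   (named list of per-group gene mean expression) and `tests`
#'   (data frame group1, group2, p_value, flagged).
#' @export
compare_cluster_expression <- function(expression, clustering, profiles,
                                       annotation, sublabels = NULL) {
  labels <- if (inherits(clustering, "cgims_clustering")) clustering$labels
            else clustering
  map <- .gene_cgi_map(annotation, profiles)
  map <- map[map$gene_id %in% rownames(expression), , drop = FALSE]
  gene_cluster <- labels[map$cgi_id]
  gmean <- rowMeans(expression)
  values <- list(reference = unname(gmean))
  for (cl in sort(unique(gene_cluster)))
    values[[paste0("cluster", cl)]] <-
      unname(gmean[map$gene_id[gene_cluster == cl]])
  if (!is.null(sublabels)) {
    gene_sub <- sublabels[map$cgi_id]
    for (s in c("3up", "3down"))
      if (any(gene_sub == s, na.rm = TRUE))
        values[[paste0("cluster", s)]] <-
          unname(gmean[map$gene_id[gene_sub == s]])
  }
  groups <- setdiff(names(values), "reference")
  pairs <- c(utils::combn(groups, 2, simplify = FALSE),
             lapply(groups, function(g) c(g, "reference")))
  tests <- do.call(rbind, lapply(pairs, function(p) {
    small <- length(values[[p[1]]]) < 2 || length(values[[p[2]]]) < 2
    pv <- if (small) NA_real_ else
      suppressWarnings(wilcox.test(values[[p[1]]], values[[p[2]]],
                                   alternative = "two.sided",
                                   exact = FALSE)$p.value)
    data.frame(group1 = p[1], group2 = p[2], p_value = pv,
               flagged = small, stringsAsFactors = FALSE)
  }))
  structure(list(values = values, tests = tests),
            class = "cgims_cluster_expression")
}

#' @export
print.cgims_cluster_expression <- function(x, ...) {
  cat("Gene mean expression by signature cluster:\n")
  for (g in names(x$values))
    cat(sprintf("  %-12s n=%4d  median %.2f\n", g, length(x$values[[g]]),
                median(x$values[[g]])))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Probewise methylation-expression correlations aggregated by region
#'
#' For each selected gene, the Pearson correlation between each probe's
#' beta values and the gene's expression across samples, pooled by the
#' probe's region label (oriented by gene strand when `orient = TRUE`, so
#' `S_shore`/`S_shelf` always mean the 3' flank). Probes with constant
#' beta have undefined correlation and are excluded (counted).
#'
#' @param x A `cgims_scores` object (the top `top_n` genes by
#'   `r2_lasso_full` are used) or a character vector of gene ids.
#' @param profiles A [build_profiles()] result.
#' @param expression Gene x sample expression matrix.
#' @param annotation Gene table (used to resolve genes when `x` is a
#'   character vector and for strand orientation).
#' @param top_n Number of top genes when `x` is a score table (default 50;
#'   the analysis is stable for 20-100).
#' @param orient Orient regions by gene strand (default `TRUE`).
#' @return Object of class `cgims_region_cor`: list with `probes` (per-probe
#'   correlations), `summary` (per-region median and quartiles) and
#'   `n_constant_excluded`.
#' @export
region_correlations <- function(x, profiles, expression, annotation,
                                top_n = 50, orient = TRUE) {
  if (inherits(x, "cgims_scores")) {
    .assert("r2_lasso_full" %in% names(x),
            "scores must contain r2_lasso_full to rank genes")
    ord <- order(-x$r2_lasso_full)
    sel <- x[ord[seq_len(min(top_n, nrow(x)))], c("gene_id", "cgi_id")]
  } else {
    .assert(length(x) > 0, "empty gene list")
    map <- .gene_cgi_map(annotation, profiles)
    sel <- map[map$gene_id %in% x, c("gene_id", "cgi_id")]
  }
  strand <- setNames(annotation$strand, annotation$gene_id)
  rows <- list()
  n_const <- 0L
  for (i in seq_len(nrow(sel))) {
    prof <- profiles[[sel$cgi_id[i]]]
    g <- sel$gene_id[i]
    samples <- intersect(colnames(expression), colnames(prof$betas))
    y <- expression[g, samples]
    B <- prof$betas[, samples, drop = FALSE]
    region <- prof$probes$region
    if (orient && identical(strand[[g]], "-")) region <- .flip_region(region)
    for (p in seq_len(nrow(B))) {
      if (sd(B[p, ]) == 0 || sd(y) == 0) { n_const <- n_const + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, cgi_id = sel$cgi_id[i],
        probe_id = prof$probes$probe_id[p], region = region[p],
        correlation = cor(B[p, ], y), stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(.REGIONS, function(r) {
    v <- probes$correlation[probes$region == r]
    data.frame(region = r, n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(probes = probes, summary = summary,
                 n_constant_excluded = n_const),
            class = "cgims_region_cor")
}

#' @export
print.cgims_region_cor <- function(x, ...) {
  cat("Probewise methylation-expression correlation by region:\n")
  print(x$summary, row.names = FALSE)
  if (x$n_constant_excluded > 0)
    cat(sprintf("(%d constant probes excluded)\n", x$n_constant_excluded))
  invisible(x)
}

#' @rdname region_correlations
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.cgims_region_cor <- function(x, ...) {
  graphics::boxplot(correlation ~ factor(region, levels = .REGIONS),
                    data = x$probes, xlab = "region (5' to 3')",
                    ylab = "Pearson correlation (beta vs expression)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Concordance of predictive scores between two conditions
#'
#' Squared Pearson correlation of per-gene predictive scores over the
#' shared gene universe — near zero when the set of
#' methylation-predictable genes shifts between tissues or between normal
#' and cancer.
#'
#' @param scores_a,scores_b `cgims_scores` objects or named numeric score
#'   vectors.
#' @param column Score column used when score tables are given (default
#'   `"r2_lasso_full"`).
#' @return List with `r_squared`, `n` and `data` (per-gene score pairs).
#' @export
cross_condition_concordance <- function(scores_a, scores_b,
                                        column = "r2_lasso_full") {
  pick <- function(s) {
    if (inherits(s, "cgims_scores")) {
      .assert(column %in% names(s), paste("missing score column:", column))
      setNames(s[[column]], s$gene_id)
    } else s
  }
  a <- pick(scores_a)
  b <- pick(scores_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  r <- cor(a[shared], b[shared])
  list(r_squared = r^2, n = length(shared),
       data = data.frame(gene_id = shared, score_a = unname(a[shared]),
                         score_b = unname(b[shared]),
                         stringsAsFactors = FALSE))
}

#' Transcription-factor enrichment of a gene set
#'
#' One-sided Fisher exact test of the 2x2 table (selected vs rest) x
#' (TF vs non-TF) over a gene universe — the exact hypergeometric tail
#' probability of seeing at least as many TFs among the selected genes.
#'
#' @param top_genes Character vector of selected genes (subset of
#'   `universe`).
#' @param tf_list Character vector of transcription-factor gene ids.
#' @param universe All scored genes.
#' @return List with `table` (2x2), `odds_ratio`, `p_value` and
#'   `degenerate` (`TRUE` when the table has an empty margin, in which
#'   case p = 1).
#' @export
tf_enrichment <- function(top_genes, tf_list, universe) {
  .assert(length(universe) > 0, "empty universe")
  .assert(all(top_genes %in% universe), "top genes must lie in the universe")
  tf <- intersect(tf_list, universe)
  is_top <- universe %in% top_genes
  is_tf <- universe %in% tf
  tab <- matrix(c(sum(is_top & is_tf), sum(is_top & !is_tf),
                  sum(!is_top & is_tf), sum(!is_top & !is_tf)),
                2, 2, dimnames = list(c("TF", "non-TF"), c("top", "rest")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1,
                degenerate = TRUE))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, degenerate = FALSE)
}
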