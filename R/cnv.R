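# Gene-level copy number from segmented log-ratio profiles, and its
# marginal / joint predictive power for expression.

#' Read a SEG file of segmented copy-number log-ratios
#'
#' Expects the standard tabular layout with columns sample, chromosome,
#' start, end, marker count and segment mean (header names are normalized;
#' the first six columns are used). Intervals are interpreted as 0-based
#' half-open.
#'
#' @param path Path to the SEG file.
#' @return Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `num_mark`, `seg_mean`.
#' @export
read_seg <- function(path) {
  seg <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  .assert(ncol(seg) >= 6, "SEG file must have at least 6 columns")
  seg <- seg[, 1:6]
  names(seg) <- c("sample", "chrom", "start", "end", "num_mark", "seg_mean")
  .assert(is.numeric(seg$start) && is.numeric(seg$end) &&
            is.numeric(seg$seg_mean), "malformed SEG file")
  seg
}

#' Gene-level copy-number scores from segments
#'
#' For each gene and sample, the segment mean log-ratio of the unique
#' segment whose half-open interval `[start, end)` contains the gene's
#' transcription start site. A TSS falling in a gap between segments is
#' assigned the nearest segment within `max_gap` base pairs; beyond that
#' the value is missing (counted in the `n_missing` attribute). More than
#' one segment covering a TSS is an error.
#'
#' @param seg Segment data frame as from [read_seg()].
#' @param annotation Gene table with `gene_id`, `chrom`, `tss`.
#' @param max_gap Maximum gap-fill distance in bp (default 1e6).
#' @return Gene x sample numeric matrix; attributes `n_gap_filled` and
#'   `n_missing`.
#' @export
gene_level_cnv <- function(seg, annotation, max_gap = 1e6) {
  .assert(all(c("sample", "chrom", "start", "end", "seg_mean") %in% names(seg)),
          "seg must have sample, chrom, start, end, seg_mean columns")
  samples <- unique(seg$sample)
  out <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  n_gap <- 0L
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(annotation))) {
      tss <- annotation$tss[i]
      cand <- ss[ss$chrom == annotation$chrom[i], , drop = FALSE]
      hit <- which(cand$start <= tss & tss < cand$end)
      if (length(hit) > 1)
        stop("overlapping segments cover the TSS of ", annotation$gene_id[i],
             " in sample ", s)
      if (length(hit) == 1) {
        out[i, s] <- cand$seg_mean[hit]
      } else if (nrow(cand) > 0) {
        d <- pmax(cand$start - tss, tss - cand$end + 1, 0)
        j <- which.min(d)
        if (d[j] <= max_gap) {
          out[i, s] <- cand$seg_mean[j]
          n_gap <- n_gap + 1L
        }
      }
    }
  }
  structure(out, n_gap_filled = n_gap, n_missing = sum(is.na(out)))
}

#' CNV-only and combined methylation+CNV predictive scores
#'
#' Computes, under the same cross-validation scheme as the methylation
#' models, the predictive R-squared of the gene's copy-number log-ratio
#' alone (univariate least squares) and of the combined predictor matrix
#' (probe betas with the CNV column appended; the penalized fit
#' standardizes all columns, so the log-ratio competes on the same scale
#' as the betas). When an existing score table with `r2_lasso_full` is
#' supplied the results are merged into it and two summaries are added:
#' the squared Pearson correlation between per-gene methylation and CNV
#' scores (near zero when the two regulatory mechanisms target different
#' genes) and paired Wilcoxon tests of the combined score against each
#' marginal.
#'
#' @param gene_cnv Gene x sample log-ratio matrix from [gene_level_cnv()].
#' @param expression Gene x sample expression matrix.
#' @param profiles A [build_profiles()] result.
#' @param annotation Gene table.
#' @param scores Optional `cgims_scores` with methylation models to merge
#'   with.
#' @param folds,repeats,seed Cross-validation scheme.
#' @return Object of class `cgims_cnv_scores`: list with `scores` (merged
#'   data frame), `independence_r2`, `wilcox_combined_vs_full` and
#'   `wilcox_combined_vs_cnv` (p-values, `NA` when not computable).
#' @export
cnv_expression_scores <- function(gene_cnv, expression, profiles, annotation,
                                  scores = NULL, folds = 3, repeats = 100,
                                  seed = NULL) {
  cnv_scores <- score_all_genes(profiles, expression, annotation,
                                models = c("ols_cnv", "lasso_combined"),
                                folds = folds, repeats = repeats, seed = seed,
                                gene_cnv = gene_cnv)
  merged <- as.data.frame(cnv_scores)
  independence <- NA_real_
  w_full <- NA_real_
  w_cnv <- NA_real_
  if (!is.null(scores)) {
    base <- as.data.frame(scores)
    merged <- merge(base, merged[, c("gene_id", "r2_ols_cnv", "r2_lasso_combined")],
                    by = "gene_id", sort = TRUE)
    if ("r2_lasso_full" %in% names(merged) && nrow(merged) >= 3) {
      independence <- cor(merged$r2_lasso_full, merged$r2_ols_cnv)^2
      w_full <- wilcox.test(merged$r2_lasso_combined, merged$r2_lasso_full,
                            paired = TRUE, exact = FALSE)$p.value
    }
    if (nrow(merged) >= 3)
      w_cnv <- wilcox.test(merged$r2_lasso_combined, merged$r2_ols_cnv,
                           paired = TRUE, exact = FALSE)$p.value
  }
  structure(list(scores = merged, independence_r2 = independence,
                 wilcox_combined_vs_full = w_full,
                 wilcox_combined_vs_cnv = w_cnv),
            class = "cgims_cnv_scores")
}

#' @export
print.cgims_cnv_scores <- function(x, ...) {
  cat(sprintf("CNV predictive scores for %d genes\n", nrow(x$scores)))
  if (!is.na(x$independence_r2))
    cat(sprintf("  methylation-R2 vs CNV-R2 correlation: R2 = %.4f\n",
                x$independence_r2))
  if (!is.na(x$wilcox_combined_vs_full))
    cat(sprintf("  combined vs methylation-only (paired Wilcoxon): p = %.3g\n",
                x$wilcox_combined_vs_full))
  if (!is.na(x$wilcox_combined_vs_cnv))
    cat(sprintf("  combined vs CNV-only (paired Wilcoxon): p = %.3g\n",
                x$wilcox_combined_vs_cnv))
  invisible(x)
}
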