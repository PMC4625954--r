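# Predictive R-squared machinery, gene scoring, region-resolved
# correlations, cross-condition concordance and TF enrichment.

test_that("predictive_r2 approaches 1 in the noiseless linear limit", {
  set.seed(1)
  n <- 100
  X <- matrix(runif(n * 5), n, 5)
  y <- 3 - 2 * X[, 3]
  expect_gte(as.numeric(predictive_r2(y, X, "lasso_full", repeats = 3, seed = 1)),
             0.99)
  expect_gte(as.numeric(predictive_r2(y, X[, 3], "ols_mean", repeats = 3, seed = 1)),
             0.99)
})

test_that("predictive_r2 stays in the null range for independent predictors", {
  set.seed(2)
  n <- 60
  scores <- replicate(10, {
    X <- matrix(runif(n * 20), n, 20)
    y <- rnorm(n)
    as.numeric(predictive_r2(y, X, "lasso_full", repeats = 3, seed = 7))
  })
  expect_lte(mean(scores), 0.05)
})

test_that("predictive_r2 is invariant to affine rescaling of expression", {
  set.seed(3)
  X <- matrix(runif(40 * 6), 40, 6)
  y <- 1 + X[, 2] + rnorm(40, 0, 0.3)
  a <- predictive_r2(y, X, "lasso_full", repeats = 4, seed = 11)
  b <- predictive_r2(5 * y - 7, X, "lasso_full", repeats = 4, seed = 11)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
})

test_that("predictive_r2 handles degenerate inputs per contract", {
  X <- matrix(runif(30), 15, 2)
  out <- predictive_r2(rep(2, 15), X, "lasso_full", repeats = 2, seed = 1)
  expect_identical(as.numeric(out), 0)
  expect_identical(attr(out, "flag"), "constant_response")
  expect_error(predictive_r2(rnorm(8), matrix(runif(16), 8, 2), "ols_mean"),
               "at least 12")
  expect_error(predictive_r2(rnorm(15), X[1:10, ], "ols_mean"),
               "sample mismatch")
})

test_that("score_all_genes separates planted from null genes and resolves CGIs", {
  coh <- small_cohort()
  prof <- small_profiles("cancer")
  sc <- fixture("small_scores", score_all_genes(
    prof, coh$expression_cancer, coh$manifest$genes,
    models = c("ols_mean", "lasso_full"), repeats = 5, seed = 13))
  df <- as.data.frame(sc)
  reg <- intersect(names(coh$truth$regulated_genes), df$gene_id)
  expect_gt(length(reg), 5)
  planted <- df$gene_id %in% reg
  expect_gt(mean(df$r2_lasso_full[planted]) - mean(df$r2_lasso_full[!planted]),
            0.3)
  # the closest-TSS rule resolves every gene to its linked CGI
  expect_identical(df$cgi_id, unname(unlist(coh$truth$primary_cgi)[df$gene_id]))
  expect_true(all(df$n_probes >= 20))
  # scores are reproducible bit-wise under the same seed
  sc2 <- score_all_genes(prof, coh$expression_cancer, coh$manifest$genes,
                         models = "lasso_full", repeats = 5, seed = 13)
  expect_identical(df$r2_lasso_full, sc2$r2_lasso_full)
  # single-model request populates only that column
  expect_false("r2_ols_mean" %in% names(sc2))
})

test_that("permuting sample labels destroys the planted scores", {
  coh <- small_cohort()
  prof <- small_profiles("cancer")
  expr <- coh$expression_cancer
  set.seed(21)
  colnames(expr) <- sample(colnames(expr))
  reg <- names(coh$truth$regulated_genes)
  ann <- coh$manifest$genes
  ann <- ann[ann$gene_id %in% reg[1:8], ]
  sc <- score_all_genes(prof, expr, ann, models = "lasso_full",
                        repeats = 5, seed = 3)
  expect_lte(mean(sc$r2_lasso_full), 0.05)
})

test_that("region_correlations recovers the planted effect region and drops constants", {
  coh <- small_cohort()
  prof <- small_profiles("cancer")
  sc <- fixture("small_scores", score_all_genes(
    prof, coh$expression_cancer, coh$manifest$genes,
    models = c("ols_mean", "lasso_full"), repeats = 5, seed = 13))
  rc <- region_correlations(sc, prof, coh$expression_cancer,
                            coh$manifest$genes, top_n = 15)
  med <- setNames(rc$summary$median, rc$summary$region)
  expect_identical(names(which.min(med)), "S_shore")

  # constant probes are excluded with a count
  p1 <- prof[[sc$cgi_id[1]]]
  prof_c <- prof
  prof_c[[sc$cgi_id[1]]]$betas[1, ] <- 0.5
  rc2 <- region_correlations(sc$gene_id[1], prof_c, coh$expression_cancer,
                             coh$manifest$genes)
  expect_identical(rc2$n_constant_excluded, 1L)
  expect_false(p1$probes$probe_id[1] %in% rc2$probes$probe_id)
})

test_that("cross_condition_concordance is exact on identity and affine maps", {
  a <- setNames(runif(20), sprintf("g%02d", 1:20))
  expect_equal(cross_condition_concordance(a, a)$r_squared, 1)
  expect_equal(cross_condition_concordance(a, 2 * a + 1)$r_squared, 1)
  expect_error(cross_condition_concordance(a[1:2], a[1:2]), "3 shared genes")
})

test_that("tf_enrichment equals the hypergeometric tail and handles degeneracy", {
  universe <- sprintf("g%04d", 1:2374)
  tf <- universe[1:100]
  top <- c(universe[1:10], universe[200:239]) # 10 TFs of 50 selected
  en <- tf_enrichment(top, tf, universe)
  # independent oracle: hypergeometric tail P(X >= 10)
  p_oracle <- sum(stats::dhyper(10:50, m = 100, n = 2274, k = 50))
  expect_equal(en$p_value, p_oracle, tolerance = 1e-12)
  expect_gt(en$odds_ratio, 1)

  deg <- tf_enrichment(universe[1:50], universe, universe)
  expect_true(deg$degenerate)
  expect_identical(deg$p_value, 1)
  expect_error(tf_enrichment("x", "x", character(0)), "empty universe")
})

test_that("compare_cluster_expression reflects planted cluster baselines", {
  coh <- small_cohort()
  prof_c <- small_profiles("cancer")
  prof_n <- small_profiles("normal")
  sig_n <- signatures(prof_n)
  sig_c <- signatures(prof_c)
  cl_n <- ward_cluster(dissimilarity_matrix(sig_n), 2, sig_n)
  cl_c <- ward_cluster(dissimilarity_matrix(sig_c), 3, sig_c)
  sub <- derive_cancer_subclusters(cl_n$labels, cl_c$labels)
  ce <- compare_cluster_expression(coh$expression_cancer, cl_c, prof_c,
                                   coh$manifest$genes, sub$sublabels)
  expect_true("cluster3up" %in% names(ce$values))
  expect_lt(median(ce$values$cluster3up), median(ce$values$cluster1))
  expect_true(all(ce$tests$p_value[!ce$tests$flagged] >= 0 &
                    ce$tests$p_value[!ce$tests$flagged] <= 1))
  # identical value sets give p ~ 1 under the tie convention
  ident <- suppressWarnings(
    stats::wilcox.test(ce$values$cluster1, ce$values$cluster1,
                       exact = FALSE)$p.value)
  expect_gt(ident, 0.99)
})
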