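# The synthetic cohort generator: config validation, manifest geometry,
# planted methylation structure, expression generative law, CNV segments
# and clinical survival data, and determinism under a fixed seed.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "cgims_simconfig")
  expect_error(sim_config(archetype_fractions = c(cluster1 = 0.5, cluster2 = 0.4,
                                                  cluster3up = 0.2, cluster3down = 0.2)),
               "sum to 1")
  expect_error(sim_config(cimp_fraction = 1.3), "CIMP")
  expect_error(sim_config(n_cgi = 0), ">= 1")
  expect_error(sim_config(beta_noise_concentration = -2), "> 0")
  expect_error(sim_config(effect_region = "upstream"), "effect_region")
})

test_that("generate_manifest lays out probes consistently with island geometry", {
  cfg <- sim_config(n_cgi = 40, probes_per_cgi_range = c(10, 40), seed = 3)
  mf <- generate_manifest(cfg)
  counts <- table(mf$probes$cgi_id)
  expect_true(any(counts < 20) && any(counts >= 20))
  for (cgi in mf$islands$cgi_id) {
    rows <- mf$probes[mf$probes$cgi_id == cgi, ]
    expect_true(all(diff(rows$pos) > 0), label = paste(cgi, "positions increasing"))
    irow <- match(cgi, mf$islands$cgi_id)
    start <- mf$islands$start[irow]
    end <- mf$islands$end[irow]
    # recompute labels from the distance rule: island [start,end),
    # shores within 2kb of the edge, shelves 2-4kb
    expected <- ifelse(rows$pos >= start & rows$pos < end, "island",
                ifelse(rows$pos >= start - 2000 & rows$pos < start, "N_shore",
                ifelse(rows$pos >= start - 4000 & rows$pos < start - 2000, "N_shelf",
                ifelse(rows$pos >= end & rows$pos < end + 2000, "S_shore", "S_shelf"))))
    expect_identical(rows$region, expected, label = cgi)
    # each region is one contiguous block along the position axis
    expect_identical(rle(rows$region)$values,
                     intersect(c("N_shelf", "N_shore", "island",
                                 "S_shore", "S_shelf"), rows$region))
  }
  # one linked gene per island, TSS adjacent to the island edge
  expect_identical(nrow(mf$genes), nrow(mf$islands))
  expect_true(all(mf$genes$strand %in% c("+", "-")))
})

test_that("manifest and full cohort are deterministic under a fixed seed", {
  cfg <- sim_config(n_cgi = 15, n_samples_normal = 6, n_samples_cancer = 8,
                    seed = 99)
  expect_identical(generate_manifest(cfg), generate_manifest(cfg))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$betas_cancer, c2$betas_cancer)
  expect_identical(c1$expression_normal, c2$expression_normal)
  expect_identical(c1$seg, c2$seg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
})

test_that("simulated methylation carries the planted archetype structure", {
  coh <- small_cohort()
  mf <- coh$manifest
  expect_true(all(coh$betas_normal >= 0 & coh$betas_normal <= 1))
  expect_true(all(coh$betas_cancer >= 0 & coh$betas_cancer <= 1))

  arch <- mf$archetypes
  pr <- mf$probes
  # cluster1 in normal condition: island hypomethylated below the shelves
  c1 <- names(arch)[arch == "cluster1"][1]
  isl_probes <- pr$probe_id[pr$cgi_id == c1 & pr$region == "island"]
  shelf_probes <- pr$probe_id[pr$cgi_id == c1 & pr$region %in% c("N_shelf", "S_shelf")]
  expect_lt(mean(coh$betas_normal[isl_probes, ]),
            mean(coh$betas_normal[shelf_probes, ]))

  # cluster3up in cancer: CIMP samples exceed non-CIMP at every island probe
  c3 <- names(arch)[arch == "cluster3up"][1]
  cimp <- coh$truth$cimp_samples
  rest <- setdiff(colnames(coh$betas_cancer), cimp)
  ip <- pr$probe_id[pr$cgi_id == c3 & pr$region == "island"]
  expect_true(all(rowMeans(coh$betas_cancer[ip, cimp, drop = FALSE]) >
                    rowMeans(coh$betas_cancer[ip, rest, drop = FALSE])))

  # CIMP subgroup size is the rounded planted fraction
  expect_identical(length(cimp),
                   as.integer(round(coh$config$cimp_fraction *
                                      coh$config$n_samples_cancer)))
})

test_that("expression follows the planted generative law", {
  # effect_size = 0 degenerates to the unregulated law: identical matrices
  cfg0 <- sim_config(n_cgi = 12, n_samples_normal = 15, seed = 5,
                     effect_size = 0)
  cfg1 <- sim_config(n_cgi = 12, n_samples_normal = 15, seed = 5,
                     effect_size = 2.5)
  mf <- generate_manifest(cfg0)
  bn <- simulate_methylation(mf, cfg0, "normal")$betas
  e0 <- simulate_expression(bn, mf, cfg0, "normal")
  e1 <- simulate_expression(bn, mf, cfg1, "normal")
  reg <- names(e1$truth$regulated_genes)
  expect_gt(length(reg), 0)
  null_genes <- setdiff(rownames(e0$expression), reg)
  expect_identical(e0$expression[null_genes, ], e1$expression[null_genes, ])
  expect_false(isTRUE(all.equal(e0$expression[reg, ], e1$expression[reg, ])))

  # single effect probe, vanishing noise: correlation(beta, expression) -> -1
  cfg <- sim_config(n_cgi = 20, n_samples_normal = 40, n_effect_probes = 1,
                    expression_noise_sd = 1e-6, seed = 8)
  mf2 <- generate_manifest(cfg)
  bn2 <- simulate_methylation(mf2, cfg, "normal")$betas
  ex <- simulate_expression(bn2, mf2, cfg, "normal")
  g <- names(ex$truth$regulated_genes)[1]
  probe <- ex$truth$regulated_genes[[g]]$probes
  expect_lt(cor(bn2[probe, ], ex$expression[g, ]), -0.999)

  # cluster3up-linked genes are lowly expressed already in normal tissue
  coh <- small_cohort()
  arch <- coh$manifest$archetypes
  primary <- unlist(coh$truth$primary_cgi)
  g3 <- names(primary)[arch[primary] == "cluster3up"]
  g1 <- names(primary)[arch[primary] == "cluster1"]
  expect_lt(mean(coh$expression_normal[g3, ]), mean(coh$expression_normal[g1, ]))

  # sample mismatch between betas and CNV is an error
  gc <- coh$gene_cnv[, rev(colnames(coh$gene_cnv))]
  expect_error(simulate_expression(coh$betas_cancer, coh$manifest, coh$config,
                                   "cancer", gene_cnv = gc),
               "mismatch")
  expect_error(simulate_methylation(coh$manifest, coh$config, "tumour"),
               "unknown condition")
})

test_that("CNV segments partition the chromosome and clinical data are valid", {
  coh <- small_cohort()
  seg <- coh$seg
  for (s in unique(seg$sample)[1:5]) {
    ss <- seg[seg$sample == s, ]
    ss <- ss[order(ss$start), ]
    expect_identical(ss$start[-1], ss$end[-nrow(ss)]) # gap- and overlap-free
    # every TSS is covered by exactly one segment
    hits <- vapply(coh$manifest$genes$tss, function(t)
      sum(ss$start <= t & t < ss$end), integer(1))
    expect_true(all(hits == 1L))
  }
  expect_true(all(is.finite(seg$seg_mean)))
  cl <- coh$clinical
  expect_true(all(cl$time > 0))
  expect_true(all(cl$event %in% c(0L, 1L)))
  expect_true(all(cl$time <= ceiling(coh$config$censor_years * 365.25)))
  expect_identical(sort(cl$sample_id), sort(colnames(coh$betas_cancer)))
})

test_that("cohorts round-trip through the plain-text writers", {
  cfg <- sim_config(n_cgi = 8, n_samples_normal = 5, n_samples_cancer = 6,
                    seed = 31)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$betas_cancer, coh$betas_cancer, tolerance = 1e-12)
  expect_equal(back$expression_normal, coh$expression_normal, tolerance = 1e-12)
  expect_identical(back$clinical, coh$clinical)
  expect_identical(unlist(back$truth$archetype_per_cgi),
                   coh$manifest$archetypes)
  expect_identical(names(back$truth$regulated_genes),
                   names(coh$truth$regulated_genes))
  expect_equal(back$gene_cnv, coh$gene_cnv, tolerance = 1e-12)
})
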