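# Synthetic cohort generator: probe manifest, beta matrices with planted
# methylation archetypes and a CIMP patient subgroup, expression driven by a
# sparse probe subset, SEG copy-number segments, and clinical survival data.

# archetype mean curve of the majority class as a function of the distance
# (kb) from the island edge: hypomethylated island, hemi-methylated shores
# rising sigmoidally into hypermethylated shelves
.c1_curve <- function(d_kb) {
  ifelse(d_kb <= 0, 0.10, 0.10 + 0.70 / (1 + exp(-2.2 * (d_kb - 1.4))))
}

# distance (kb) of probe positions from the island interval edge; 0 inside
.edge_distance_kb <- function(pos, start, end) {
  ifelse(pos < start, (start - pos) / 1000,
         ifelse(pos >= end, (pos - end + 1) / 1000, 0))
}

.region_from_position <- function(pos, start, end) {
  ifelse(pos >= start & pos < end, "island",
  ifelse(pos >= start - 2000 & pos < start, "N_shore",
  ifelse(pos >= start - 4000 & pos < start - 2000, "N_shelf",
  ifelse(pos >= end & pos < end + 2000, "S_shore",
  ifelse(pos >= end + 2000 & pos < end + 4000, "S_shelf", NA_character_)))))
}

#' Generate a synthetic probe manifest, island set and gene annotation
#'
#' Lays out `n_cgi` CpG islands on one chromosome, places probes at strictly
#' increasing positions across the island, its shores (up to 2kb from the
#' island edge) and shelves (2-4kb), labels each probe with its region, and
#' links one gene (TSS adjacent to the island, random strand) to each island.
#' Each CGI+SS is also assigned a methylation archetype
#' (cluster1/cluster2/cluster3up/cluster3down) drawn from
#' `config$archetype_fractions`; the assignment is part of the ground truth
#' used by [simulate_methylation()].
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cgims_sim_manifest`: list with `probes`
#'   (probe_id, chrom, pos, cgi_id, region), `islands` (cgi_id, chrom,
#'   start, end; 0-based half-open), `genes` (gene_id, chrom, tss, strand,
#'   cgi_ids), and `archetypes` (named character vector per CGI).
#' @examples
#' mf <- generate_manifest(sim_config(n_cgi = 5))
#' table(mf$probes$region)
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "cgims_simconfig"))
  set.seed(config$seed)
  n <- config$n_cgi
  cgi_ids <- sprintf("CGI%04d", seq_len(n))
  width <- round(runif(n, 600, 1400))
  start <- 20000 + (seq_len(n) - 1) * 60000
  end <- start + width
  rng <- config$probes_per_cgi_range
  n_probes <- sample(seq.int(rng[1], rng[2]), n, replace = TRUE)

  # split the probe budget over the five regions, at least one probe each
  # (island gets the largest share, as on the 450K design)
  region_share <- c(N_shelf = 0.15, N_shore = 0.15, island = 0.40,
                    S_shore = 0.15, S_shelf = 0.15)
  probe_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cnt <- round(n_probes[i] * region_share)
    cnt[cnt < 1] <- 1L
    while (sum(cnt) > n_probes[i]) cnt["island"] <- cnt["island"] - 1L
    while (sum(cnt) < n_probes[i]) cnt["island"] <- cnt["island"] + 1L
    bounds <- list(
      N_shelf = c(start[i] - 4000, start[i] - 2001),
      N_shore = c(start[i] - 2000, start[i] - 1),
      island  = c(start[i], end[i] - 1),
      S_shore = c(end[i], end[i] + 1999),
      S_shelf = c(end[i] + 2000, end[i] + 3999))
    pos <- unlist(lapply(.REGIONS, function(r) {
      sort(sample(seq.int(bounds[[r]][1], bounds[[r]][2]), cnt[[r]]))
    }), use.names = FALSE)
    probe_rows[[i]] <- data.frame(
      chrom = "chr1", pos = pos, cgi_id = cgi_ids[i],
      region = .region_from_position(pos, start[i], end[i]),
      stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  probes$probe_id <- sprintf("cg%06d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos", "cgi_id", "region")]

  islands <- data.frame(cgi_id = cgi_ids, chrom = "chr1",
                        start = start, end = end, stringsAsFactors = FALSE)

  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start - 100, end + 100)
  cgi_links <- as.list(cgi_ids)
  if (config$multi_cgi_fraction > 0 && n >= 2) {
    extra <- which(runif(n) < config$multi_cgi_fraction)
    for (i in extra) cgi_links[[i]] <- c(cgi_ids[i], cgi_ids[i %% n + 1])
  }
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)), chrom = "chr1",
    tss = tss, strand = strand,
    cgi_ids = vapply(cgi_links, paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  archetypes <- setNames(
    sample(names(config$archetype_fractions), n, replace = TRUE,
           prob = config$archetype_fractions),
    cgi_ids)

  structure(list(probes = probes, islands = islands, genes = genes,
                 archetypes = archetypes),
            class = "cgims_sim_manifest")
}

#' @export
print.cgims_sim_manifest <- function(x, ...) {
  cat(sprintf("Synthetic manifest: %d probes across %d CGI+SS, %d genes\n",
              nrow(x$probes), nrow(x$islands), nrow(x$genes)))
  print(table(archetype = x$archetypes))
  invisible(x)
}

# per-sample island hypermethylation penetrance of the CIMP strata
.CIMP_ALPHA <- c(low = 0, intermediate = 0.5, high = 0.93)

#' Simulate probe-level methylation beta values
#'
#' Draws a probes x samples beta matrix around the archetype mean curves:
#' cluster1 profiles are hypomethylated in the island (~0.1) rising through
#' hemi-methylated shores to hypermethylated shelves (~0.8); cluster2 is
#' uniformly hypermethylated; cluster3up keeps the cluster1 shape in normal
#' tissue and gains island/shore methylation in cancer, but only in the CIMP
#' patient strata (intermediate: partial; high: near-full), so the
#' population mean is hemi-methylated while per-sample values are bimodal;
#' cluster3down is cluster2-shaped in normal tissue and partially island-
#' demethylated in every cancer sample. Each (sample, CGI, region) receives
#' a Gaussian level shift (`region_level_sd`) creating inter-individual
#' variation, and probe values are Beta(mean*c, (1-mean)*c) draws with
#' concentration `beta_noise_concentration`, so betas stay in [0,1].
#'
#' @param manifest A [generate_manifest()] result.
#' @param config The [sim_config()] used for the manifest.
#' @param condition `"normal"` or `"cancer"`.
#' @return List with `betas` (probes x samples matrix) and `truth` (list:
#'   `archetype_per_cgi`, and for cancer `cimp_samples` — the high stratum —
#'   plus `cimp_levels`, the low/intermediate/high label per sample).
#' @export
simulate_methylation <- function(manifest, config, condition) {
  stopifnot(inherits(manifest, "cgims_sim_manifest"),
            inherits(config, "cgims_simconfig"))
  if (!condition %in% c("normal", "cancer"))
    stop("unknown condition label: ", condition)
  n_s <- if (condition == "normal") config$n_samples_normal else config$n_samples_cancer
  samples <- sprintf("%s%03d", if (condition == "normal") "N" else "C", seq_len(n_s))
  set.seed(.sub_seed(config$seed, if (condition == "normal") 101 else 202))

  cimp_levels <- setNames(rep("low", n_s), samples)
  if (condition == "cancer") {
    n_high <- round(config$cimp_fraction * n_s)
    n_int <- round(config$cimp_intermediate_fraction * n_s)
    picked <- sample(samples, n_high + n_int)
    cimp_levels[picked[seq_len(n_high)]] <- "high"
    if (n_int > 0) cimp_levels[picked[n_high + seq_len(n_int)]] <- "intermediate"
  }
  alpha <- .CIMP_ALPHA[cimp_levels]

  pr <- manifest$probes
  isl <- manifest$islands
  betas <- matrix(NA_real_, nrow(pr), n_s,
                  dimnames = list(pr$probe_id, samples))
  conc <- config$beta_noise_concentration
  for (ci in seq_len(nrow(isl))) {
    idx <- which(pr$cgi_id == isl$cgi_id[ci])
    d_kb <- .edge_distance_kb(pr$pos[idx], isl$start[ci], isl$end[ci])
    base <- .c1_curve(d_kb)
    arche <- manifest$archetypes[[isl$cgi_id[ci]]]
    # probes x samples matrix of archetype means
    mu <- switch(arche,
      cluster1 = matrix(base, length(idx), n_s),
      cluster2 = matrix(0.80, length(idx), n_s),
      cluster3up = {
        a <- if (condition == "cancer") alpha else rep(0, n_s)
        outer(0.80 - base, a) + base  # base + a * (0.8 - base)
      },
      cluster3down = {
        if (condition == "cancer") matrix(0.80 - 0.5 * (0.80 - base), length(idx), n_s)
        else matrix(0.80, length(idx), n_s)
      })
    # shared per-(sample, region) level shifts: inter-individual variation
    u <- matrix(rnorm(5L * n_s, 0, config$region_level_sd), 5L, n_s,
                dimnames = list(.REGIONS, samples))
    mu <- mu + u[pr$region[idx], , drop = FALSE]
    mu <- pmin(pmax(mu, 0.02), 0.98)
    betas[idx, ] <- matrix(rbeta(length(mu), mu * conc, (1 - mu) * conc),
                           nrow(mu), ncol(mu))
  }
  truth <- list(archetype_per_cgi = manifest$archetypes,
                condition = condition)
  if (condition == "cancer") {
    truth$cimp_samples <- names(cimp_levels)[cimp_levels == "high"]
    truth$cimp_levels <- cimp_levels
  }
  list(betas = betas, truth = truth)
}

# deterministic gene-level ground truth shared by both conditions: which
# genes are methylation-regulated (effect probes + weights), per-gene
# baselines, and which genes carry the CNV dosage term
.gene_truth <- function(manifest, config) {
  set.seed(.sub_seed(config$seed, 303))
  genes <- manifest$genes
  isl <- manifest$islands
  mid <- setNames((isl$start + isl$end) / 2, isl$cgi_id)
  counts <- table(manifest$probes$cgi_id)

  primary <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    linked <- strsplit(genes$cgi_ids[i], ",", fixed = TRUE)[[1]]
    primary[i] <- linked[which.min(abs(mid[linked] - genes$tss[i]))]
  }
  names(primary) <- genes$gene_id

  # oriented effect region -> genomic region per strand
  eff_region_genomic <- ifelse(genes$strand == "-",
                               .flip_region(config$effect_region),
                               config$effect_region)
  eligible <- vapply(seq_len(nrow(genes)), function(i) {
    cgi <- primary[i]
    if (manifest$archetypes[[cgi]] == "cluster3up") return(FALSE)
    if (counts[[cgi]] < 20) return(FALSE)
    sum(manifest$probes$cgi_id == cgi &
          manifest$probes$region == eff_region_genomic[i]) >= config$n_effect_probes
  }, logical(1))

  n_reg <- min(config$n_regulated_genes, sum(eligible))
  reg_ids <- sort(sample(genes$gene_id[eligible], n_reg))
  regulated <- lapply(setNames(reg_ids, reg_ids), function(g) {
    i <- match(g, genes$gene_id)
    cand <- manifest$probes$probe_id[manifest$probes$cgi_id == primary[g] &
                                       manifest$probes$region == eff_region_genomic[i]]
    probes <- sort(cand[sample.int(length(cand), config$n_effect_probes)])
    list(probes = probes,
         weights = setNames(runif(length(probes), 0.5, 1.5), probes))
  })

  baselines <- setNames(rnorm(nrow(genes), config$baseline_mean, config$baseline_sd),
                        genes$gene_id)
  is3up <- manifest$archetypes[primary] == "cluster3up"
  baselines[is3up] <- baselines[is3up] + config$baseline_3up_shift

  if (config$cnv_gene_fraction >= 1) {
    cnv_genes <- genes$gene_id
  } else {
    pool <- if (config$cnv_disjoint) setdiff(genes$gene_id, reg_ids) else genes$gene_id
    n_cnv <- min(round(config$cnv_gene_fraction * nrow(genes)), length(pool))
    cnv_genes <- sort(pool[sample.int(length(pool), n_cnv)])
  }
  list(primary_cgi = primary, regulated_genes = regulated,
       baselines = baselines, cnv_genes = cnv_genes)
}

#' Simulate gene expression from methylation and copy number
#'
#' Expression (log2 scale) is `baseline + cnv_effect_size * log-ratio at the
#' TSS` for CNV-affected genes, minus
#' `effect_size * sum(weight_j * beta_j)` over the effect probes for
#' methylation-regulated genes (weights positive: methylation represses),
#' plus Gaussian noise. Genes linked to a cluster-3up CGI+SS receive a low
#' baseline in both conditions, independent of their methylation, and are
#' never methylation-regulated.
#'
#' @param betas Probe x sample beta matrix from [simulate_methylation()].
#' @param manifest The [generate_manifest()] result.
#' @param config The shared [sim_config()].
#' @param condition `"normal"` or `"cancer"` (noise stream differs).
#' @param gene_cnv Optional gene x sample matrix of segment log-ratios (from
#'   [gene_level_cnv()]); `NULL` means diploid (no dosage term).
#' @return List with `expression` (genes x samples matrix) and `truth`
#'   (regulated genes with effect probes/weights, CNV-affected genes,
#'   baselines, primary CGI per gene).
#' @export
simulate_expression <- function(betas, manifest, config, condition,
                                gene_cnv = NULL) {
  stopifnot(inherits(manifest, "cgims_sim_manifest"))
  if (!condition %in% c("normal", "cancer"))
    stop("unknown condition label: ", condition)
  samples <- colnames(betas)
  if (!is.null(gene_cnv) && !identical(colnames(gene_cnv), samples))
    stop("sample mismatch between beta matrix and gene-level CNV")
  gt <- .gene_truth(manifest, config)
  set.seed(.sub_seed(config$seed, if (condition == "normal") 404 else 454))

  genes <- manifest$genes$gene_id
  expr <- matrix(rnorm(length(genes) * length(samples), 0,
                       config$expression_noise_sd),
                 length(genes), length(samples),
                 dimnames = list(genes, samples))
  expr <- expr + gt$baselines[genes]
  if (!is.null(gene_cnv)) {
    hit <- intersect(gt$cnv_genes, rownames(gene_cnv))
    expr[hit, ] <- expr[hit, ] +
      config$cnv_effect_size * gene_cnv[hit, samples, drop = FALSE]
  }
  for (g in names(gt$regulated_genes)) {
    eff <- gt$regulated_genes[[g]]
    contrib <- colSums(eff$weights * betas[eff$probes, samples, drop = FALSE])
    expr[g, ] <- expr[g, ] - config$effect_size * contrib
  }
  list(expression = expr, truth = gt)
}

#' Simulate copy-number segments and clinical survival data
#'
#' Copy number: per sample, the chromosome is partitioned into
#' piecewise-constant segments (Poisson number of breakpoints) whose
#' log-ratios are 0 with probability 0.6 and Gaussian gains/losses
#' otherwise, independent of the methylation truth. Clinical: exponential
#' survival times whose hazard is `baseline_hazard` multiplied by the
#' planted hazard ratio of each sample's CIMP stratum
#' (low 1, intermediate `hazard_ratio_intermediate`, high
#' `hazard_ratio_high`), administratively censored at `censor_years`;
#' ER/HER2/lymph-node status, age and tumour size are drawn independently
#' of survival.
#'
#' @param manifest The [generate_manifest()] result.
#' @param truth Methylation truth for the cancer condition (needs
#'   `cimp_levels`).
#' @param config The shared [sim_config()].
#' @param samples Sample ids to simulate (defaults to the names of
#'   `truth$cimp_levels`).
#' @return List with `seg` (sample, chrom, start, end, num_mark, seg_mean;
#'   0-based half-open), `clinical` (sample_id, time in days, event, ER,
#'   HER2, node, age, size) and `planted_hr`.
#' @export
simulate_cnv_and_clinical <- function(manifest, truth, config,
                                      samples = NULL) {
  stopifnot(inherits(manifest, "cgims_sim_manifest"))
  samples <- samples %||% names(truth$cimp_levels)
  .assert(length(samples) >= 1, "no samples to simulate")
  set.seed(.sub_seed(config$seed, 505))
  L <- as.integer(max(manifest$islands$end) + 50000)

  seg_rows <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    k <- rpois(1, 6)
    breaks <- if (k > 0) sort(sample.int(L - 1, min(k, L - 1))) else integer(0)
    b0 <- c(0L, breaks)
    b1 <- c(breaks, L)
    nseg <- length(b0)
    mean_lr <- ifelse(runif(nseg) < 0.6, 0, rnorm(nseg, 0, 0.4))
    seg_rows[[si]] <- data.frame(
      sample = samples[si], chrom = "chr1", start = b0, end = b1,
      num_mark = as.integer(pmax(5, round((b1 - b0) / 2000))),
      seg_mean = mean_lr, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_rows)

  levels_ <- truth$cimp_levels[samples]
  levels_[is.na(levels_)] <- "low"
  planted_hr <- c(low = 1,
                  intermediate = config$hazard_ratio_intermediate,
                  high = config$hazard_ratio_high)
  rate <- config$baseline_hazard * planted_hr[levels_]
  t_years <- rexp(length(samples), rate = rate)
  event <- as.integer(t_years < config$censor_years)
  time_days <- as.integer(round(pmin(t_years, config$censor_years) * 365.25))
  time_days[time_days == 0L] <- 1L
  clinical <- data.frame(
    sample_id = samples,
    time = time_days,
    event = event,
    ER = sample(c("+", "-"), length(samples), replace = TRUE, prob = c(0.65, 0.35)),
    HER2 = sample(c("+", "-"), length(samples), replace = TRUE, prob = c(0.2, 0.8)),
    node = sample(c("pos", "neg"), length(samples), replace = TRUE, prob = c(0.4, 0.6)),
    age = as.integer(pmin(pmax(round(rnorm(length(samples), 58, 12)), 25), 90)),
    size = pmin(pmax(round(rnorm(length(samples), 25, 10), 1), 5), 80),
    stringsAsFactors = FALSE)
  list(seg = seg, clinical = clinical, planted_hr = planted_hr)
}

#' Simulate a complete matched cohort
#'
#' Runs the full generator: manifest, normal and cancer methylation,
#' copy-number segments and clinical data for the cancer samples, gene-level
#' CNV scores, and expression for both conditions (the cancer expression
#' includes the dosage term). All stages derive their randomness from
#' `config$seed`, so the cohort is reproducible bit-for-bit.
#'
#' @param config A [sim_config()].
#' @return Object of class `cgims_cohort`: list with `manifest`,
#'   `betas_normal`, `betas_cancer`, `expression_normal`,
#'   `expression_cancer`, `seg`, `clinical`, `gene_cnv` and `truth` (the
#'   merged ground-truth record).
#' @examples
#' coh <- simulate_cohort(sim_config(n_cgi = 10, n_samples_normal = 8,
#'                                   n_samples_cancer = 8, seed = 7))
#' dim(coh$betas_cancer)
#' @export
simulate_cohort <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  mn <- simulate_methylation(manifest, config, "normal")
  mc <- simulate_methylation(manifest, config, "cancer")
  cc <- simulate_cnv_and_clinical(manifest, mc$truth, config,
                                  samples = colnames(mc$betas))
  gene_cnv <- gene_level_cnv(cc$seg, manifest$genes)
  en <- simulate_expression(mn$betas, manifest, config, "normal")
  ec <- simulate_expression(mc$betas, manifest, config, "cancer",
                            gene_cnv = gene_cnv)
  truth <- list(
    archetype_per_cgi = as.list(manifest$archetypes),
    probe_count_per_cgi = as.list(table(manifest$probes$cgi_id)),
    cimp_samples = mc$truth$cimp_samples,
    cimp_levels = as.list(mc$truth$cimp_levels),
    regulated_genes = ec$truth$regulated_genes,
    cnv_genes = ec$truth$cnv_genes,
    primary_cgi = as.list(ec$truth$primary_cgi),
    planted_hr = as.list(cc$planted_hr))
  structure(list(manifest = manifest,
                 betas_normal = mn$betas, betas_cancer = mc$betas,
                 expression_normal = en$expression,
                 expression_cancer = ec$expression,
                 seg = cc$seg, clinical = cc$clinical,
                 gene_cnv = gene_cnv, truth = truth, config = config),
            class = "cgims_cohort")
}

#' @export
print.cgims_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d CGI+SS, %d probes, %d genes\n",
              nrow(x$manifest$islands), nrow(x$manifest$probes),
              nrow(x$manifest$genes)))
  cat(sprintf("  %d normal / %d cancer samples; %d CIMP-high samples\n",
              ncol(x$betas_normal), ncol(x$betas_cancer),
              length(x$truth$cimp_samples)))
  cat(sprintf("  %d methylation-regulated genes; %d CNV-affected genes\n",
              length(x$truth$regulated_genes), length(x$truth$cnv_genes)))
  invisible(x)
}
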