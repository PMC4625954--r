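# Plain-text readers/writers for the cohort tables: TSV matrices, a BED
# island file, a SEG copy-number file and a JSON ground-truth record.

# full_precision formats doubles with 17 significant digits so that
# values round-trip through text exactly (needed when a written table is
# read back as computation input)
.write_tsv <- function(df, path, full_precision = FALSE) {
  if (full_precision) {
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

.write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path, full_precision = is.double(m))
}

.read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the probe manifest, island BED, gene annotation, beta and
#' expression matrices, SEG copy-number file, clinical table and the
#' ground-truth JSON into `dir`. All files are deterministic given the
#' cohort.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cgims_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_tsv(cohort$manifest$probes, p("manifest.tsv"))
  isl <- cohort$manifest$islands
  write.table(isl[, c("chrom", "start", "end", "cgi_id")], p("islands.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_tsv(cohort$manifest$genes, p("annotation.tsv"))
  .write_matrix_tsv(cohort$betas_normal, p("betas_normal.tsv"), "probe_id")
  .write_matrix_tsv(cohort$betas_cancer, p("betas_cancer.tsv"), "probe_id")
  .write_matrix_tsv(cohort$expression_normal, p("expression_normal.tsv"), "gene_id")
  .write_matrix_tsv(cohort$expression_cancer, p("expression_cancer.tsv"), "gene_id")
  .write_tsv(cohort$seg, p("cnv.seg"), full_precision = TRUE)
  .write_tsv(cohort$clinical, p("clinical.tsv"), full_precision = TRUE)
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(cohort$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @return A `cgims_cohort` list (the simulation manifest is reassembled,
#'   including the archetype truth).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("manifest.tsv", "islands.bed", "annotation.tsv",
              "betas_normal.tsv", "betas_cancer.tsv",
              "expression_normal.tsv", "expression_cancer.tsv",
              "cnv.seg", "clinical.tsv", "truth.json"))
    if (!file.exists(p(f))) stop("missing cohort file: ", p(f))
  probes <- .read_tsv(p("manifest.tsv"))
  islands <- read.table(p("islands.bed"), sep = "\t", stringsAsFactors = FALSE,
                        col.names = c("chrom", "start", "end", "cgi_id"))
  islands <- islands[, c("cgi_id", "chrom", "start", "end")]
  genes <- .read_tsv(p("annotation.tsv"))
  truth <- jsonlite::fromJSON(p("truth.json"), simplifyVector = TRUE)
  truth$archetype_per_cgi <- unlist(truth$archetype_per_cgi)
  truth$probe_count_per_cgi <- unlist(truth$probe_count_per_cgi)
  truth$cimp_levels <- unlist(truth$cimp_levels)
  truth$primary_cgi <- unlist(truth$primary_cgi)
  truth$planted_hr <- unlist(truth$planted_hr)
  truth$regulated_genes <- lapply(truth$regulated_genes, function(g)
    list(probes = unlist(g$probes), weights = unlist(g$weights)))
  manifest <- structure(list(probes = probes, islands = islands,
                             genes = genes,
                             archetypes = truth$archetype_per_cgi),
                        class = "cgims_sim_manifest")
  seg <- .read_tsv(p("cnv.seg"))
  config <- if (file.exists(p("config.json")))
    jsonlite::fromJSON(p("config.json"), simplifyVector = TRUE) else NULL
  structure(list(manifest = manifest,
                 betas_normal = .read_matrix_tsv(p("betas_normal.tsv")),
                 betas_cancer = .read_matrix_tsv(p("betas_cancer.tsv")),
                 expression_normal = .read_matrix_tsv(p("expression_normal.tsv")),
                 expression_cancer = .read_matrix_tsv(p("expression_cancer.tsv")),
                 seg = seg,
                 clinical = .read_tsv(p("clinical.tsv")),
                 gene_cnv = gene_level_cnv(seg, genes),
                 truth = truth, config = config),
            class = "cgims_cohort")
}
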