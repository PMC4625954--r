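# Assemble per-CGI+SS methylation profiles from probe-level beta values:
# group probes (island + shores + shelves) by CGI, handle missing data,
# apply the minimum-probe filter, and reduce sample sets to mean signatures.

#' Build CGI+SS methylation profiles from a beta matrix
#'
#' Groups measured probes by CGI (islands together with their shore and
#' shelf probes), sorts them by genomic position, applies the missing-data
#' rule (probes missing in more than `max_missing` of samples are dropped,
#' remaining gaps are mean-imputed so profile lengths stay equal across
#' samples), and retains only profiles with at least `min_probes` probes —
#' profiles with fewer probes cannot resolve within-CGI methylation
#' variation and are excluded from all downstream analysis.
#'
#' @param betas Probe x sample matrix of beta values in `[0,1]`; rownames
#'   are probe ids.
#' @param manifest A `cgims_sim_manifest` or a probe data frame with columns
#'   `probe_id`, `chrom`, `pos`, `cgi_id`, `region`.
#' @param islands Island intervals (`cgi_id`, `chrom`, `start`, `end`;
#'   0-based half-open). Taken from `manifest` when it is a simulation
#'   manifest.
#' @param annotation Gene table (`gene_id`, `chrom`, `tss`, `strand`,
#'   `cgi_ids` comma-separated). Taken from `manifest` when available.
#' @param min_probes Minimum probe count for a profile to be retained
#'   (default 20).
#' @param max_missing Maximum tolerated fraction of missing samples per
#'   probe before the probe is dropped (default 0.1).
#' @return Object of class `cgims_profiles`: a named list of profiles, each
#'   with `cgi_id`, `chrom`, `probes` (probe_id, pos, region), `betas`
#'   (complete probe x sample matrix), `island` (start, end) and `genes`
#'   (linked gene_id, tss, strand). Attribute `dropped` records the CGI ids
#'   removed by the probe filter.
#' @export
build_profiles <- function(betas, manifest, islands = NULL, annotation = NULL,
                           min_probes = 20, max_missing = 0.1) {
  if (inherits(manifest, "cgims_sim_manifest")) {
    islands <- islands %||% manifest$islands
    annotation <- annotation %||% manifest$genes
    manifest <- manifest$probes
  }
  .assert(is.data.frame(manifest) &&
            all(c("probe_id", "pos", "cgi_id", "region") %in% names(manifest)),
          "manifest must provide probe_id, pos, cgi_id and region columns")
  .assert(!is.null(islands), "island intervals are required")

  if (nrow(betas) == 0)
    return(structure(setNames(list(), character(0)),
                     dropped = character(0), class = "cgims_profiles"))
  unknown <- setdiff(rownames(betas), manifest$probe_id)
  if (length(unknown) > 0)
    stop("probes present in the beta matrix but absent from the manifest: ",
         paste(head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10))

  mf <- manifest[manifest$probe_id %in% rownames(betas), , drop = FALSE]
  profiles <- list()
  dropped <- character(0)
  for (cgi in unique(mf$cgi_id)) {
    rows <- mf[mf$cgi_id == cgi, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    if (anyDuplicated(rows$pos))
      stop("duplicated probe positions within ", cgi)
    B <- betas[rows$probe_id, , drop = FALSE]
    miss <- rowMeans(is.na(B))
    keep <- miss <= max_missing & miss < 1
    rows <- rows[keep, , drop = FALSE]
    B <- B[keep, , drop = FALSE]
    if (anyNA(B)) { # mean imputation keeps profile lengths equal across samples
      rm <- rowMeans(B, na.rm = TRUE)
      idx <- which(is.na(B), arr.ind = TRUE)
      B[idx] <- rm[idx[, 1]]
    }
    if (nrow(rows) < min_probes) {
      dropped <- c(dropped, cgi)
      next
    }
    irow <- match(cgi, islands$cgi_id)
    genes <- NULL
    if (!is.null(annotation)) {
      hit <- vapply(strsplit(annotation$cgi_ids, ",", fixed = TRUE),
                    function(v) cgi %in% v, logical(1))
      genes <- annotation[hit, c("gene_id", "tss", "strand"), drop = FALSE]
    }
    profiles[[cgi]] <- list(
      cgi_id = cgi,
      chrom = rows$chrom[1] %||% NA_character_,
      probes = rows[, c("probe_id", "pos", "region")],
      betas = B,
      island = if (!is.na(irow)) c(start = islands$start[irow],
                                   end = islands$end[irow]) else NULL,
      genes = genes)
  }
  structure(profiles, dropped = dropped, class = "cgims_profiles")
}

#' @export
print.cgims_profiles <- function(x, ...) {
  np <- vapply(x, function(p) nrow(p$probes), integer(1))
  cat(sprintf("%d CGI+SS profiles (%s probes each; %d dropped by the probe filter)\n",
              length(x),
              if (length(x)) paste0(min(np), "-", max(np)) else "0",
              length(attr(x, "dropped"))))
  invisible(x)
}

#' @export
`[.cgims_profiles` <- function(x, i) {
  structure(NextMethod(), dropped = attr(x, "dropped"),
            class = "cgims_profiles")
}

#' Mean methylation signature of one profile over a sample set
#'
#' The signature of a CGI+SS is the vector pair (probe positions, per-probe
#' mean beta across the chosen samples), ordered by genomic position — the
#' object the DTW distance compares.
#'
#' @param profile One element of a [build_profiles()] result.
#' @param samples Character vector of sample ids (default: all samples).
#' @param condition Optional condition tag carried on the signature.
#' @return Object of class `cgims_signature`: list with `cgi_id`, `X`
#'   (positions), `Y` (mean betas), `n`, `region` (per-probe labels),
#'   `island` and `condition`.
#' @export
mean_signature <- function(profile, samples = NULL, condition = NULL) {
  samples <- samples %||% colnames(profile$betas)
  .assert(length(samples) > 0, "empty sample subset")
  missing_s <- setdiff(samples, colnames(profile$betas))
  .assert(length(missing_s) == 0,
          paste("samples absent from profile:",
                paste(head(missing_s, 5), collapse = ", ")))
  structure(list(cgi_id = profile$cgi_id,
                 X = profile$probes$pos,
                 Y = unname(rowMeans(profile$betas[, samples, drop = FALSE])),
                 n = nrow(profile$probes),
                 region = profile$probes$region,
                 island = profile$island,
                 condition = condition),
            class = "cgims_signature")
}

#' @export
print.cgims_signature <- function(x, ...) {
  cat(sprintf("CGI+SS signature %s: %d probes, beta %.2f-%.2f%s\n",
              x$cgi_id, x$n, min(x$Y), max(x$Y),
              if (!is.null(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Standardize a signature onto normalized CGI coordinates
#'
#' Maps probe positions onto an axis where the island spans `[0, 1]`
#' regardless of its true width and flank positions are measured in kb from
#' the island edge: a probe d bp upstream of the island start maps to
#' `-d/1000` (so the shore covers (0, 2] and the shelf (2, 4] on each side)
#' and a probe d bp downstream of the island end maps to `1 + d/1000`. For
#' genes on the minus strand the axis is reflected (`coord -> 1 - coord`)
#' and shore/shelf labels swapped, so positive coordinates beyond the island
#' are always 3' of the gene.
#'
#' @param signature A [mean_signature()] result.
#' @param island Island interval `c(start, end)`; defaults to the interval
#'   carried on the signature.
#' @param strand `"+"` or `"-"`.
#' @return A `cgims_signature` with `X` replaced by normalized coordinates
#'   (still strictly increasing) and regions oriented by strand.
#' @export
standardize_axis <- function(signature, island = NULL, strand = "+") {
  island <- island %||% signature$island
  .assert(!is.null(island) && length(island) == 2 && island[1] < island[2],
          "island interval must be c(start, end) with start < end")
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  x <- signature$X
  if (island[1] < min(x) - 4000 || island[2] > max(x) + 4000 ||
      island[2] < min(x) || island[1] > max(x))
    stop("island interval outside profile span")
  start <- island[1]; end <- island[2]
  coord <- ifelse(x < start, -(start - x) / 1000,
           ifelse(x >= end, 1 + (x - end) / 1000,
                  (x - start) / (end - start)))
  region <- signature$region
  if (strand == "-") {
    coord <- 1 - coord
    if (!is.null(region)) region <- .flip_region(region)
  }
  ord <- order(coord)
  out <- signature
  out$X <- coord[ord]
  out$Y <- signature$Y[ord]
  if (!is.null(region)) out$region <- region[ord]
  attr(out, "standardized") <- TRUE
  out
}

#' Mean signatures for every profile
#'
#' @param profiles A [build_profiles()] result.
#' @param samples Optional sample subset passed to [mean_signature()].
#' @param condition Optional condition tag.
#' @return Named list of `cgims_signature` objects.
#' @export
signatures <- function(profiles, samples = NULL, condition = NULL) {
  lapply(profiles, mean_signature, samples = samples, condition = condition)
}
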