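# Ward clustering of CGI+SS signatures on the DTW dissimilarity matrix,
# bootstrap stability for choosing the number of clusters, medoid-based
# cluster summaries, and the normal-vs-cancer 3up/3down sub-cluster logic.

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the classical Ward (Lance-Williams)
#' criterion applied to the dissimilarity matrix directly
#' (`stats::hclust(method = "ward.D")`; the DTW costs are already sums of
#' squared differences, so they are not squared again), cut at `k`
#' clusters. When signatures are supplied, clusters are relabelled
#' canonically by their mean island methylation: cluster 1 is the most
#' island-hypomethylated group, cluster 2 the most hypermethylated, and any
#' remaining clusters are numbered from 3 upward by ascending island
#' methylation — so "cluster 3" is the intermediate, hemi-methylated class,
#' reproducibly, regardless of the arbitrary dendrogram cut order.
#'
#' @param D Symmetric dissimilarity matrix (e.g. [dissimilarity_matrix()]).
#' @param k Number of clusters, `1 <= k <= nrow(D)`.
#' @param signatures Optional list of `cgims_signature` objects parallel to
#'   `D` (used for the canonical relabelling; must carry `region` labels).
#' @return Object of class `cgims_clustering`: list with `labels` (named
#'   integer vector), `k`, `hclust` (the merge tree), `island_mean`
#'   (per-item island methylation, if available) and `canonical` flag.
#' @export
ward_cluster <- function(D, k, signatures = NULL) {
  .assert(is.matrix(D) && nrow(D) == ncol(D), "D must be a square matrix")
  n <- nrow(D)
  .assert(k >= 1 && k <= n, sprintf("k must lie in [1, %d]", n))
  hc <- hclust(as.dist(D), method = "ward.D")
  raw <- cutree(hc, k = k)
  if (!is.null(rownames(D))) names(raw) <- rownames(D)

  island_mean <- NULL
  canonical <- FALSE
  labels <- raw
  if (!is.null(signatures) &&
      all(vapply(signatures, function(s) !is.null(s$region), logical(1)))) {
    island_mean <- vapply(signatures, function(s) {
      idx <- s$region == "island"
      if (any(idx)) mean(s$Y[idx]) else mean(s$Y)
    }, numeric(1))
    cl_mean <- tapply(island_mean, raw, mean)
    ord <- order(cl_mean) # ascending island methylation
    new_id <- integer(length(ord))
    new_id[ord[1]] <- 1L
    if (k >= 2) new_id[ord[length(ord)]] <- 2L
    if (k >= 3) new_id[ord[seq(2, length(ord) - 1)]] <- seq(3L, k)
    labels <- setNames(new_id[match(raw, as.integer(names(cl_mean)))], names(raw))
    canonical <- TRUE
  }
  structure(list(labels = labels, k = k, hclust = hc,
                 island_mean = island_mean, canonical = canonical),
            class = "cgims_clustering")
}

#' @export
print.cgims_clustering <- function(x, ...) {
  cat(sprintf("Ward clustering at k=%d%s\n", x$k,
              if (x$canonical) " (canonical labels: 1=hypo, 2=hyper, 3+=intermediate)" else ""))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Fowlkes-Mallows similarity between two partitions
#'
#' Geometric mean of pairwise precision and recall over co-clustered item
#' pairs. Returns `NA` when either partition has no co-clustered pair.
#'
#' @param a,b Cluster label vectors over the same items.
#' @return Similarity in `[0, 1]`, or `NA` for degenerate partitions.
#' @export
fowlkes_mallows <- function(a, b) {
  .assert(length(a) == length(b), "partitions must cover the same items")
  n <- length(a)
  ct <- table(a, b)
  Tk <- sum(ct^2) - n
  Pk <- sum(rowSums(ct)^2) - n
  Qk <- sum(colSums(ct)^2) - n
  if (Pk == 0 || Qk == 0) return(NA_real_)
  Tk / sqrt(Pk * Qk)
}

#' Bootstrap stability of the cluster number
#'
#' For each repeat, two independent subsamples of `subsample` x 100% of the
#' items are drawn, each is Ward-clustered at every `k`, and the
#' Fowlkes-Mallows similarity of the two partitions is computed on the
#' intersection of the subsamples; stability(k) is the mean over repeats.
#' The selected `k` is the largest one whose mean stability exceeds
#' `threshold` (`NA` if none does — callers typically fall back to the
#' most stable `k`).
#'
#' If all pairwise dissimilarities are (numerically) zero the items carry
#' no cluster structure: any split is arbitrary, stability is undefined,
#' and a flagged result with `NA` scores is returned.
#'
#' @param D Dissimilarity matrix.
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_repeats Bootstrap repeats (default 100).
#' @param subsample Subsampling ratio (default 0.8).
#' @param threshold Stability threshold for selection (default 0.9).
#' @param seed Optional seed for the subsample draws.
#' @return Object of class `cgims_stability`: list with `scores`
#'   (data.frame k, stability), `selected_k`, `degenerate` flag and the
#'   parameters.
#' @export
bootstrap_stability <- function(D, k_range = 2:6, n_repeats = 100,
                                subsample = 0.8, threshold = 0.9,
                                seed = NULL) {
  .assert(is.matrix(D) && nrow(D) == ncol(D), "D must be a square matrix")
  n <- nrow(D)
  ssize <- floor(subsample * n)
  .assert(all(k_range >= 2) && all(k_range <= ssize),
          sprintf("k_range must lie in [2, %d]", ssize))
  if (max(D) < 1e-12) {
    return(structure(list(scores = data.frame(k = k_range, stability = NA_real_),
                          selected_k = NA_integer_, degenerate = TRUE,
                          n_repeats = n_repeats, subsample = subsample,
                          threshold = threshold),
                     class = "cgims_stability"))
  }
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(NA_real_, n_repeats, length(k_range))
  for (r in seq_len(n_repeats)) {
    s1 <- sort(sample.int(n, ssize))
    s2 <- sort(sample.int(n, ssize))
    common <- intersect(s1, s2)
    if (length(common) < 2) next
    c1 <- cutree(hclust(as.dist(D[s1, s1]), "ward.D"), k = k_range)
    c2 <- cutree(hclust(as.dist(D[s2, s2]), "ward.D"), k = k_range)
    i1 <- match(common, s1)
    i2 <- match(common, s2)
    for (j in seq_along(k_range))
      acc[r, j] <- fowlkes_mallows(c1[i1, j], c2[i2, j])
  }
  stab <- colMeans(acc, na.rm = TRUE)
  ok <- which(stab > threshold)
  structure(list(scores = data.frame(k = k_range, stability = stab),
                 selected_k = if (length(ok)) max(k_range[ok]) else NA_integer_,
                 degenerate = FALSE,
                 n_repeats = n_repeats, subsample = subsample,
                 threshold = threshold),
            class = "cgims_stability")
}

#' @export
print.cgims_stability <- function(x, ...) {
  if (x$degenerate) {
    cat("Bootstrap stability: degenerate input (all dissimilarities zero)\n")
    return(invisible(x))
  }
  cat(sprintf("Bootstrap stability (%d repeats, %.0f%% subsamples):\n",
              x$n_repeats, 100 * x$subsample))
  print(x$scores, row.names = FALSE)
  cat(sprintf("selected k (largest with stability > %.2f): %s\n",
              x$threshold, x$selected_k))
  invisible(x)
}

#' Medoid members of each cluster
#'
#' The `n_medoids` items of each cluster with the smallest total
#' dissimilarity to their co-members, in ascending order (so the first
#' entry is the classical medoid). Clusters smaller than `n_medoids`
#' return all their members and are flagged.
#'
#' @param D Dissimilarity matrix with dimnames.
#' @param labels Cluster labels (named, parallel to `D`).
#' @param n_medoids Medoids per cluster (default 10).
#' @return Named list (per cluster) of item id vectors; attribute
#'   `flagged` lists clusters smaller than `n_medoids`.
#' @export
medoid_profiles <- function(D, labels, n_medoids = 10) {
  .assert(length(labels) == nrow(D), "labels must be parallel to D")
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  out <- list()
  flagged <- character(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    rs <- rowSums(D[idx, idx, drop = FALSE])
    ord <- idx[order(rs, ids[idx])]
    take <- min(n_medoids, length(ord))
    if (length(ord) < n_medoids) flagged <- c(flagged, as.character(cl))
    out[[as.character(cl)]] <- ids[ord[seq_len(take)]]
  }
  attr(out, "flagged") <- flagged
  out
}

#' Derive cancer-specific 3up/3down sub-clusters and concordance tables
#'
#' CGI+SS assigned to the cancer-specific cluster 3 are split by their
#' normal-tissue class: "3up" if they sit in the hypomethylated cluster 1
#' of the matched normal condition (they gained methylation in cancer),
#' "3down" if in the hypermethylated cluster 2 (they lost it); everything
#' else is "none". Also returns the contingency table of (normal x cancer)
#' labels; the same table applies across tissue pairs.
#'
#' @param normal_labels,cancer_labels Named cluster label vectors over the
#'   same CGI+SS universe (canonical labels, see [ward_cluster()]).
#' @return Object of class `cgims_subclusters`: list with `sublabels`
#'   (named character: "3up"/"3down"/"none") and `concordance` (table).
#' @export
derive_cancer_subclusters <- function(normal_labels, cancer_labels) {
  .assert(!is.null(names(normal_labels)) && !is.null(names(cancer_labels)),
          "label vectors must be named by CGI id")
  if (!setequal(names(normal_labels), names(cancer_labels)) ||
      length(normal_labels) != length(cancer_labels))
    stop("universe mismatch between normal and cancer assignments")
  ids <- names(normal_labels)
  ca <- cancer_labels[ids]
  sub <- ifelse(ca == 3 & normal_labels == 1, "3up",
                ifelse(ca == 3 & normal_labels == 2, "3down", "none"))
  names(sub) <- ids
  conc <- table(normal = normal_labels, cancer = ca)
  structure(list(sublabels = sub, concordance = conc),
            class = "cgims_subclusters")
}

#' @export
print.cgims_subclusters <- function(x, ...) {
  cat("Cancer-specific sub-clusters:\n")
  print(table(x$sublabels))
  cat("Normal x cancer concordance:\n")
  print(x$concordance)
  invisible(x)
}

#' Condensed cluster profiles from medoid signatures
#'
#' Places the medoid signatures of each cluster on the standardized CGI
#' axis (island mapped to `[0, 1]`, flanks in signed kb; oriented by the
#' linked gene's strand when `orient = TRUE`), yielding the plotting data
#' for per-cluster characteristic shapes.
#'
#' @param profiles A [build_profiles()] result.
#' @param clustering A [ward_cluster()] result over the same profiles.
#' @param D The dissimilarity matrix used for clustering.
#' @param samples Optional sample subset for the signature means.
#' @param n_medoids Medoids per cluster (default 10).
#' @param orient Reflect minus-strand profiles so that positive flank
#'   coordinates are 3' of the gene (default `TRUE`).
#' @return Data frame with columns `cluster`, `cgi_id`, `coord`, `beta`,
#'   `region`.
#' @export
condensed_profiles <- function(profiles, clustering, D, samples = NULL,
                               n_medoids = 10, orient = TRUE) {
  med <- medoid_profiles(D, clustering$labels, n_medoids)
  rows <- list()
  for (cl in names(med)) {
    for (cgi in med[[cl]]) {
      p <- profiles[[cgi]]
      strand <- if (orient && !is.null(p$genes) && nrow(p$genes) > 0)
        p$genes$strand[1] else "+"
      sig <- standardize_axis(mean_signature(p, samples), strand = strand)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, cgi_id = cgi, coord = sig$X, beta = sig$Y,
        region = sig$region, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot condensed cluster profiles
#'
#' @param x A [condensed_profiles()] data frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_condensed_profiles <- function(x, ...) {
  cls <- sort(unique(x$cluster))
  cols <- setNames(grDevices::hcl.colors(max(3, length(cls)), "Dark 3")[seq_along(cls)], cls)
  graphics::plot(x$coord, x$beta, type = "n", xlab = "standardized CGI coordinate",
                 ylab = "mean beta", ylim = c(0, 1), ...)
  graphics::abline(v = c(0, 1), lty = 2, col = "orange")
  graphics::abline(v = c(-2, 3), lty = 2, col = "steelblue")
  for (cl in cls) {
    sub <- x[x$cluster == cl, ]
    for (cgi in unique(sub$cgi_id)) {
      s <- sub[sub$cgi_id == cgi, ]
      graphics::lines(s$coord, s$beta, col = cols[[cl]])
    }
  }
  graphics::legend("bottomright", legend = paste("cluster", cls),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
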