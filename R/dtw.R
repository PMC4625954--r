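# Dynamic time warping between methylation signatures. The cost is the sum
# of squared beta differences along a monotone alignment path; probe
# positions are not part of the cost — they matter only for axis
# standardization and region labelling.

.BOUNDARY_CODES <- c(partial = 0L, fixed = 1L, printed = 2L)

.sig_y <- function(s, arg) {
  y <- if (inherits(s, "cgims_signature")) s$Y else s
  .assert(is.numeric(y) && length(y) > 0, paste("empty signature:", arg))
  .assert(!anyNA(y) && all(is.finite(y)), paste("non-finite values in", arg))
  y
}

#' DTW distance between two methylation signatures
#'
#' Minimum over admissible warping paths of the summed squared differences
#' between aligned mean beta values. A path is a sequence of index pairs
#' into the two signatures in which each index advances by 0 or 1 per step
#' (at least one advancing). The `boundary` argument selects the admissible
#' start/end cells:
#'
#' * `"partial"` (default): free start on the first element of either
#'   signature and free end on the last element of either (open
#'   begin/open end). Note this admits single-cell paths at the grid
#'   corners, so two profiles whose terminal probes agree can be at
#'   distance ~0 regardless of their interior shape.
#' * `"fixed"`: classical endpoints — the path starts at (1,1) and ends at
#'   (m,n), covering both signatures completely. This is the variant used
#'   by [dissimilarity_matrix()] for clustering, precisely because the
#'   open-ended variant degenerates for profiles that all share
#'   hypermethylated shelves at both ends.
#' * `"printed"`: free start as in `"partial"`, end on cells whose first
#'   index equals the *second* signature's length or whose second index
#'   does (an asymmetric form retained for comparison; symmetrise at the
#'   matrix level).
#'
#' @param sig1,sig2 `cgims_signature` objects or bare numeric vectors of
#'   mean beta values.
#' @param boundary Boundary condition, see above.
#' @param normalize If `TRUE`, divide the optimal raw cost by the length of
#'   its path (the raw sum is the default).
#' @return Non-negative numeric distance.
#' @examples
#' dtw_distance(c(0.1, 0.2, 0.8), c(0.1, 0.2, 0.8))      # 0
#' dtw_distance(c(0, 0, 0), c(1, 1, 1))                  # 1: corner path
#' dtw_distance(c(0, 0, 0), c(1, 1, 1), boundary = "fixed") # 3: full cover
#' @export
dtw_distance <- function(sig1, sig2,
                         boundary = c("partial", "fixed", "printed"),
                         normalize = FALSE) {
  boundary <- match.arg(boundary)
  y1 <- .sig_y(sig1, "sig1")
  y2 <- .sig_y(sig2, "sig2")
  .dtw_cost(y1, y2, .BOUNDARY_CODES[[boundary]], isTRUE(normalize))
}

#' Pairwise DTW dissimilarity matrix over a set of signatures
#'
#' Applies [dtw_distance()] to every pair and returns a symmetric matrix
#' with zero diagonal. For the `"printed"` boundary variant, which is not
#' symmetric in its arguments, the two directions are averaged; the
#' `"partial"` and `"fixed"` variants are exactly symmetric by
#' construction.
#'
#' The default boundary here is `"fixed"`, unlike [dtw_distance()]: for
#' clustering, every profile must be covered end-to-end, otherwise all
#' CGI+SS — which share hypermethylated shelves at both extremities —
#' collapse to near-zero mutual distances through single-cell corner
#' alignments and no shape structure survives.
#'
#' @param sigs List of `cgims_signature` objects or numeric vectors
#'   (length >= 2). Names become dimnames.
#' @param boundary,normalize Passed to the underlying DTW (see
#'   [dtw_distance()]).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(sigs, boundary = "fixed", normalize = FALSE) {
  .assert(is.list(sigs) && length(sigs) >= 2, "need at least 2 signatures")
  boundary <- match.arg(boundary, names(.BOUNDARY_CODES))
  ys <- lapply(seq_along(sigs), function(i) .sig_y(sigs[[i]], paste0("sigs[[", i, "]]")))
  D <- .dtw_matrix(ys, .BOUNDARY_CODES[[boundary]], isTRUE(normalize))
  ids <- names(sigs) %||%
    vapply(sigs, function(s) if (inherits(s, "cgims_signature")) s$cgi_id else NA_character_, "")
  if (!anyNA(ids) && length(unique(ids)) == length(sigs))
    dimnames(D) <- list(ids, ids)
  D
}
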