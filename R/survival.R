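# CIMP-style patient stratification on cluster-3up methylation and its
# prognostic value: Kaplan-Meier curves with the log-rank test, and a
# multivariate Cox proportional hazards model over standard breast-cancer
# clinical covariates.

#' Stratify patients by mean methylation of the cancer-specific CGI+SS
#'
#' Each patient is summarized by the vector of per-CGI+SS mean betas over
#' the CGI+SS carrying the requested sub-cluster label (default "3up", the
#' islands hypomethylated in normal tissue that gain methylation in
#' cancer). Patients are Ward-clustered on these vectors (Euclidean
#' distance — the vectors are positionless per-island means, so DTW does
#' not apply) and the `k = 3` groups are relabelled low / intermediate /
#' high by ascending grand mean methylation. The "high" group is the
#' CIMP-like hypermethylator phenotype; "intermediate" corresponds to the
#' partial (CIMP-low) phenotype.
#'
#' @param profiles A [build_profiles()] result (cancer condition).
#' @param sublabels Named "3up"/"3down"/"none" vector from
#'   [derive_cancer_subclusters()], or a character vector of CGI ids.
#' @param samples Sample ids to stratify (default: all columns of the
#'   first selected profile).
#' @param k Number of strata (default 3).
#' @param target Sub-cluster label selecting the CGI+SS set (default
#'   "3up").
#' @return Object of class `cgims_strata`: data frame with `sample_id`,
#'   `mean_methylation` (grand mean over the selected CGI+SS) and
#'   `stratum` (ordered factor); attributes `matrix` (sample x CGI means)
#'   and `degenerate` flag (all-identical samples).
#' @export
stratify_patients <- function(profiles, sublabels, samples = NULL, k = 3,
                              target = "3up") {
  cgis <- if (!is.null(names(sublabels)))
    names(sublabels)[sublabels == target] else sublabels
  cgis <- intersect(cgis, names(profiles))
  if (length(cgis) == 0) stop("no CGI+SS with sub-cluster label ", target)
  samples <- samples %||% colnames(profiles[[cgis[1]]]$betas)
  if (length(samples) < 3) stop("need at least 3 samples to stratify")
  M <- vapply(cgis, function(cgi)
    colMeans(profiles[[cgi]]$betas[, samples, drop = FALSE]), numeric(length(samples)))
  M <- matrix(M, nrow = length(samples), dimnames = list(samples, cgis))
  degenerate <- max(dist(M)) < 1e-12
  if (degenerate) {
    strata <- factor(rep("low", length(samples)),
                     levels = c("low", "intermediate", "high"))
  } else {
    hc <- hclust(dist(M), method = "ward.D2")
    raw <- cutree(hc, k = k)
    grand <- rowMeans(M)
    lvl_names <- if (k == 3) c("low", "intermediate", "high")
                 else paste0("level", seq_len(k))
    ord <- order(tapply(grand, raw, mean)) # ascending methylation
    lab <- character(k)
    lab[ord] <- lvl_names
    strata <- factor(lab[raw], levels = lvl_names)
  }
  structure(data.frame(sample_id = samples,
                       mean_methylation = unname(rowMeans(M)),
                       stratum = strata, stringsAsFactors = FALSE),
            matrix = M, degenerate = degenerate,
            class = c("cgims_strata", "data.frame"))
}

#' @export
print.cgims_strata <- function(x, ...) {
  cat(sprintf("Patient strata over %d CGI+SS:\n", ncol(attr(x, "matrix"))))
  agg <- tapply(x$mean_methylation, x$stratum, mean)
  for (s in levels(x$stratum))
    cat(sprintf("  %-12s n=%3d  mean methylation %.3f\n", s,
                sum(x$stratum == s), agg[[s]]))
  if (isTRUE(attr(x, "degenerate")))
    cat("  [degenerate: all samples identical, no clustering performed]\n")
  invisible(x)
}

.merge_clinical <- function(strata, clinical, window_days = NULL) {
  df <- merge(as.data.frame(strata), clinical, by = "sample_id")
  .assert(nrow(df) > 0, "no samples shared between strata and clinical table")
  .assert(all(df$time > 0), "survival times must be positive")
  if (!is.null(window_days)) {
    over <- df$time > window_days
    df$event[over] <- 0L
    df$time[over] <- window_days
  }
  df
}

#' Kaplan-Meier curves and log-rank test across methylation strata
#'
#' Product-limit survival estimates per stratum and the k-group log-rank
#' test. Strata in which no event occurred are flagged (their curves are
#' still produced); with a single stratum no test is run.
#'
#' @param strata A [stratify_patients()] result.
#' @param clinical Clinical table with `sample_id`, `time` (days) and
#'   `event` (1 = death within window).
#' @param window_days Optional administrative censoring window in days
#'   (e.g. 5 years = 1826).
#' @return Object of class `cgims_km`: list with `fit` (survfit), `curves`
#'   (data frame time, n_risk, n_event, survival, stratum), `p_value`
#'   (log-rank; `NA` with a single stratum) and `flagged` (event-free
#'   strata).
#' @export
km_logrank <- function(strata, clinical, window_days = NULL) {
  df <- .merge_clinical(strata, clinical, window_days)
  df$stratum <- droplevels(df$stratum)
  events <- tapply(df$event, df$stratum, sum)
  flagged <- names(events)[events == 0]
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  sm <- summary(fit)
  curves <- data.frame(
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv,
    stratum = if (!is.null(sm$strata))
      sub("^stratum=", "", as.character(sm$strata))
    else rep(levels(df$stratum)[1], length(sm$time)),
    stringsAsFactors = FALSE)
  p <- NA_real_
  if (nlevels(df$stratum) >= 2) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
    p <- pchisq(lr$chisq, df = nlevels(df$stratum) - 1, lower.tail = FALSE)
  }
  structure(list(fit = fit, curves = curves, p_value = p, flagged = flagged,
                 n = nrow(df)),
            class = "cgims_km")
}

#' @export
print.cgims_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate over %d patients\n", x$n))
  if (!is.na(x$p_value)) cat(sprintf("  log-rank p = %.4g\n", x$p_value))
  if (length(x$flagged))
    cat("  event-free strata:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `cgims_km` object.
#' @param ... Passed to the survfit plot method.
#' @export
plot.cgims_km <- function(x, ...) {
  ns <- length(x$fit$strata %||% 1)
  graphics::plot(x$fit, col = seq_len(ns), xlab = "days",
                 ylab = "overall survival", ...)
  if (!is.null(x$fit$strata))
    graphics::legend("bottomleft", legend = sub("^stratum=", "", names(x$fit$strata)),
                     col = seq_len(ns), lty = 1, bty = "n")
  invisible(x)
}

#' Multivariate Cox proportional hazards model
#'
#' Fits `Surv(time, event) ~ stratum + (ER,HER2) + node + age + size` by
#' partial likelihood (Efron tie handling): the methylation stratum
#' (reference "low"), the combined hormone/HER2 receptor factor
#' (reference "-/-"), lymph-node status (reference negative), and age and
#' tumour size as continuous covariates. Factor levels with no events
#' cannot be estimated — their coefficient diverges and the Wald CI is
#' (0, Inf); such levels are detected and flagged rather than failing.
#' A singular design (aliased columns) is an error naming the collinear
#' terms.
#'
#' @param strata A [stratify_patients()] result (or any data frame with
#'   `sample_id` and a `stratum` factor).
#' @param clinical Clinical table (`sample_id`, `time`, `event`, `ER`,
#'   `HER2`, `node`, `age`, `size`).
#' @param window_days Optional administrative censoring window in days.
#' @param covariates Clinical covariates entering the model besides the
#'   stratum; any subset of `"er_her2"`, `"node"`, `"age"`, `"size"`
#'   (default: all).
#' @return Object of class `cgims_cox`: data frame with `term`, `hr`,
#'   `lower`, `upper` (95% Wald CI), `p_value`, `flagged`; the `coxph`
#'   fit is kept in the `fit` attribute.
#' @export
cox_multivariate <- function(strata, clinical, window_days = NULL,
                             covariates = c("er_her2", "node", "age",
                                            "size")) {
  if (length(covariates))
    covariates <- match.arg(covariates, several.ok = TRUE)
  df <- .merge_clinical(strata, clinical, window_days)
  df$stratum <- droplevels(df$stratum)
  if ("er_her2" %in% covariates) {
    df$er_her2 <- factor(paste0(df$ER, "/", df$HER2),
                         levels = c("-/-", "+/-", "-/+", "+/+"))
    df$er_her2 <- droplevels(df$er_her2)
  }
  if ("node" %in% covariates)
    df$node <- factor(df$node, levels = c("neg", "pos"))
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(c("stratum", covariates), collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron")
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  degenerate <- abs(cf) > 10 | se > 100 # diverging level, e.g. no events
  out <- data.frame(
    term = names(cf),
    hr = exp(cf),
    lower = exp(cf - 1.96 * se),
    upper = exp(cf + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(cf / se)),
    flagged = degenerate,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$lower[degenerate] <- 0
  out$upper[degenerate] <- Inf
  structure(out, fit = fit, class = c("cgims_cox", "data.frame"))
}

#' @export
print.cgims_cox <- function(x, ...) {
  cat("Multivariate Cox proportional hazards model\n")
  df <- as.data.frame(x)
  df$hr <- sprintf("%.3g", df$hr)
  df$ci <- sprintf("(%.3g-%.3g)", x$lower, x$upper)
  df$p_value <- sprintf("%.3g", x$p_value)
  print(df[, c("term", "hr", "ci", "p_value", "flagged")], row.names = FALSE)
  invisible(x)
}
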