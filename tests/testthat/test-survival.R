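# Patient stratification on cluster-3up methylation, Kaplan-Meier /
# log-rank, and the multivariate Cox model with its degeneracy handling.

# minimal strata object for direct survival-model tests
make_strata <- function(ids, stratum) {
  structure(data.frame(sample_id = ids, mean_methylation = 0,
                       stratum = factor(stratum,
                                        levels = c("low", "intermediate", "high")),
                       stringsAsFactors = FALSE),
            matrix = matrix(0, length(ids), 1), degenerate = FALSE,
            class = c("cgims_strata", "data.frame"))
}

make_clinical <- function(ids, time, event, ER = "+", HER2 = "-",
                          node = "neg", age = 60, size = 25) {
  data.frame(sample_id = ids, time = time, event = event, ER = ER,
             HER2 = HER2, node = node, age = age, size = size,
             stringsAsFactors = FALSE)
}

test_that("stratify_patients recovers the planted CIMP strata", {
  coh <- small_cohort()
  prof <- small_profiles("cancer")
  sig_n <- signatures(small_profiles("normal"))
  sig_c <- signatures(prof)
  cl_n <- ward_cluster(dissimilarity_matrix(sig_n), 2, sig_n)
  cl_c <- ward_cluster(dissimilarity_matrix(sig_c), 3, sig_c)
  sub <- derive_cancer_subclusters(cl_n$labels, cl_c$labels)
  st <- stratify_patients(prof, sub$sublabels)
  lev <- unlist(coh$truth$cimp_levels)[st$sample_id]
  # planted high-penetrance samples concentrate in the "high" stratum
  expect_gte(mean(st$stratum[lev == "high"] == "high"), 0.9)
  expect_gte(mean(st$stratum[lev == "low"] == "low"), 0.9)
  # relabelling is invariant to sample order
  perm <- rev(st$sample_id)
  st2 <- stratify_patients(prof, sub$sublabels, samples = perm)
  expect_identical(setNames(as.character(st2$stratum), st2$sample_id)[st$sample_id],
                   setNames(as.character(st$stratum), st$sample_id))

  expect_error(stratify_patients(prof, sub$sublabels, samples = perm[1:2]),
               "at least 3")
  none <- setNames(rep("none", 3), names(sub$sublabels)[1:3])
  expect_error(stratify_patients(prof, none), "no CGI\\+SS")
})

test_that("stratify_patients flags all-identical patients as degenerate", {
  prof <- small_profiles("cancer")
  prof_c <- prof
  for (i in seq_along(prof_c)) prof_c[[i]]$betas[] <- 0.4
  lab <- setNames("3up", names(prof_c)[1])
  st <- stratify_patients(prof_c, lab)
  expect_true(attr(st, "degenerate"))
})

test_that("KM estimate equals the empirical survival function without censoring", {
  set.seed(5)
  n <- 40
  ids <- sprintf("p%02d", 1:n)
  time <- sort(round(rexp(n, 0.01)) + 1) + seq_len(n) # distinct times
  st <- make_strata(ids, rep("low", n))
  km <- km_logrank(st, make_clinical(ids, time, rep(1L, n)))
  emp <- vapply(km$curves$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$curves$survival, emp, tolerance = 1e-12)
  expect_true(is.na(km$p_value)) # single stratum: no test
})

test_that("log-rank separates extreme groups and flags event-free strata", {
  ids <- sprintf("p%03d", 1:100)
  # all events in the low group happen before any in the intermediate group
  time <- c(1:50, 101:150)
  st <- make_strata(ids, rep(c("low", "intermediate"), each = 50))
  km <- km_logrank(st, make_clinical(ids, time, rep(1L, 100)))
  expect_lt(km$p_value, 1e-4)

  ev <- c(rep(1L, 50), rep(0L, 50))
  km2 <- km_logrank(st, make_clinical(ids, time, ev))
  expect_identical(km2$flagged, "intermediate")
})

test_that("cox_multivariate agrees with a partial-likelihood oracle", {
  set.seed(6)
  n <- 80
  ids <- sprintf("p%03d", 1:n)
  x <- rep(c(0, 1), each = n / 2)
  time <- rexp(n, 0.02 * exp(0.8 * x)) * 100 # continuous: no ties a.s.
  st <- make_strata(ids, ifelse(x == 1, "high", "low"))
  cox <- cox_multivariate(st, make_clinical(ids, time, rep(1L, n)),
                          covariates = character(0))
  b_oracle <- cox_oracle_coef(time, rep(1L, n), x)
  expect_equal(log(cox$hr[cox$term == "stratumhigh"]), b_oracle,
               tolerance = 1e-6)
})

test_that("cox_multivariate flags inestimable factor levels", {
  set.seed(7)
  n <- 120
  ids <- sprintf("p%03d", 1:n)
  time <- rexp(n, 0.01) * 10 + 1
  ER <- rep(c("-", "+"), each = n / 2)
  HER2 <- rep("-", n)
  HER2[1:10] <- "+"
  event <- rep(1L, n)
  event[HER2 == "+"] <- 0L # the -/+ cell has no events: inestimable level
  st <- make_strata(ids, rep(c("low", "high"), n / 2))
  cl <- make_clinical(ids, time, event, ER = ER, HER2 = HER2,
                      node = sample(c("neg", "pos"), n, replace = TRUE),
                      age = rnorm(n, 60, 10), size = rnorm(n, 25, 8))
  cox <- cox_multivariate(st, cl)
  bad <- cox[cox$term == "er_her2-/+", ]
  expect_true(bad$flagged)
  expect_identical(bad$lower, 0)
  expect_identical(bad$upper, Inf)
  expect_false(any(cox$flagged[cox$term %in% c("stratumhigh", "age", "size")]))
})

test_that("a null covariate's hazard-ratio CI covers 1", {
  set.seed(8)
  n <- 300
  ids <- sprintf("p%03d", 1:n)
  time <- rexp(n, 0.02) * 100
  st <- make_strata(ids, sample(c("low", "high"), n, replace = TRUE))
  cox <- cox_multivariate(st, make_clinical(ids, time, rep(1L, n),
                                            age = rnorm(n, 60, 10),
                                            size = rnorm(n, 25, 8)),
                          covariates = c("age", "size"))
  for (trm in c("stratumhigh", "age", "size")) {
    row <- cox[cox$term == trm, ]
    expect_lte(row$lower, 1.05)
    expect_gte(row$upper, 0.95)
  }
})
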