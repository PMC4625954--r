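# Ward clustering on the DTW matrix, canonical archetype labelling,
# bootstrap stability, medoids, and the 3up/3down sub-cluster logic.

# noisy constant-level signatures around the given means
level_signatures <- function(means, n_probes = 12, sd = 0.01, seed = 1) {
  set.seed(seed)
  sigs <- lapply(seq_along(means), function(i)
    pmin(pmax(rnorm(n_probes, means[i], sd), 0), 1))
  names(sigs) <- sprintf("sig%03d", seq_along(means))
  sigs
}

test_that("ward_cluster recovers planted separation and honours k limits", {
  truth <- rep(1:2, each = 15)
  sigs <- level_signatures(c(0.1, 0.9)[truth])
  D <- dissimilarity_matrix(sigs)
  cl <- ward_cluster(D, 2)
  expect_identical(length(unique(cl$labels[truth == 1])), 1L)
  expect_identical(length(unique(cl$labels[truth == 2])), 1L)
  expect_false(unique(cl$labels[truth == 1]) == unique(cl$labels[truth == 2]))

  expect_identical(unname(ward_cluster(D, 1)$labels), rep(1L, 30))
  expect_identical(sort(unname(ward_cluster(D, 30)$labels)), 1:30)
  expect_error(ward_cluster(D, 31), "k must lie")
})

test_that("canonical labels order clusters as hypo=1, hyper=2, intermediate=3", {
  # three archetype levels with island/shelf structure
  mk_sig <- function(island_level, id) {
    y <- c(0.8, 0.8, rep(island_level, 6), 0.8, 0.8)
    structure(list(cgi_id = id, X = seq_along(y) * 100, Y = y, n = length(y),
                   region = c("N_shelf", "N_shore", rep("island", 6),
                              "S_shore", "S_shelf"),
                   island = NULL, condition = NULL),
              class = "cgims_signature")
  }
  set.seed(4)
  levels_ <- rep(c(0.1, 0.8, 0.45), each = 8) # hypo, hyper, hemi
  sigs <- lapply(seq_along(levels_), function(i)
    mk_sig(min(max(levels_[i] + rnorm(1, 0, 0.01), 0), 1), sprintf("c%02d", i)))
  names(sigs) <- vapply(sigs, `[[`, "", "cgi_id")
  D <- dissimilarity_matrix(sigs)
  cl <- ward_cluster(D, 3, signatures = sigs)
  expect_true(cl$canonical)
  expect_identical(unname(cl$labels[1:8]), rep(1L, 8))    # hypo islands
  expect_identical(unname(cl$labels[9:16]), rep(2L, 8))   # hyper
  expect_identical(unname(cl$labels[17:24]), rep(3L, 8))  # hemi
})

test_that("cluster labels are invariant to input order after canonical relabelling", {
  coh <- small_cohort()
  prof <- small_profiles("cancer")
  sigs <- signatures(prof)
  D <- dissimilarity_matrix(sigs)
  cl <- ward_cluster(D, 3, signatures = sigs)
  perm <- sample(seq_along(sigs))
  cl_p <- ward_cluster(D[perm, perm], 3, signatures = sigs[perm])
  expect_identical(cl$labels[names(cl_p$labels)], cl_p$labels)
})

test_that("medoid_profiles ranks members by within-cluster total distance", {
  # 3-point cluster with a known centre
  D <- matrix(c(0, 1, 1,
                1, 0, 1.8,
                1, 1.8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  med <- medoid_profiles(D, setNames(rep(1L, 3), c("a", "b", "c")),
                         n_medoids = 1)
  expect_identical(med[["1"]], "a")          # min row sum: the medoid
  med3 <- medoid_profiles(D, setNames(rep(1L, 3), c("a", "b", "c")),
                          n_medoids = 10)
  expect_identical(med3[["1"]], c("a", "b", "c")) # all members, flagged
  expect_identical(attr(med3, "flagged"), "1")
  # brute-force row sums agree with the returned order
  expect_identical(med3[["1"]], names(sort(rowSums(D))))
})

test_that("fowlkes_mallows behaves on identical, refined and degenerate partitions", {
  a <- rep(1:3, each = 4)
  expect_equal(fowlkes_mallows(a, a), 1)
  expect_lt(fowlkes_mallows(a, rep(1:6, each = 2)), 1)
  expect_true(is.na(fowlkes_mallows(1:6, 1:6))) # all singletons: undefined
})

test_that("bootstrap_stability is reproducible and flags degenerate input", {
  sigs <- level_signatures(rep(c(0.1, 0.9), each = 10))
  D <- dissimilarity_matrix(sigs)
  s1 <- bootstrap_stability(D, k_range = 2:3, n_repeats = 5, seed = 42)
  s2 <- bootstrap_stability(D, k_range = 2:3, n_repeats = 5, seed = 42)
  expect_identical(s1$scores, s2$scores)
  expect_gt(s1$scores$stability[s1$scores$k == 2], 0.95)

  Dz <- matrix(0, 10, 10)
  sz <- bootstrap_stability(Dz, k_range = 2:3, n_repeats = 3)
  expect_true(sz$degenerate)
  expect_true(all(is.na(sz$scores$stability)))

  expect_error(bootstrap_stability(D, k_range = 2:30), "k_range")
})

test_that("derive_cancer_subclusters implements the 3up/3down definition", {
  ids <- sprintf("cg%02d", 1:8)
  normal <- setNames(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L), ids)
  cancer <- setNames(c(1L, 3L, 2L, 3L, 1L, 2L, 3L, 3L), ids)
  sub <- derive_cancer_subclusters(normal, cancer)
  # normal cluster 1 + cancer cluster 3 -> 3up
  expect_identical(unname(sub$sublabels[c("cg02", "cg07")]), c("3up", "3up"))
  # normal cluster 2 + cancer cluster 3 -> 3down
  expect_identical(unname(sub$sublabels[c("cg04", "cg08")]), c("3down", "3down"))
  # stable assignments -> none
  expect_identical(unname(sub$sublabels["cg01"]), "none")
  # contingency table conserves cluster sizes
  expect_identical(unname(rowSums(sub$concordance)),
                   as.numeric(table(normal)))
  expect_identical(unname(colSums(sub$concordance)),
                   as.numeric(table(cancer)))

  expect_error(derive_cancer_subclusters(normal, cancer[1:7]),
               "universe mismatch")
})

test_that("condensed_profiles returns standardized medoid shapes per cluster", {
  prof <- small_profiles("cancer")
  sigs <- signatures(prof)
  D <- dissimilarity_matrix(sigs)
  cl <- ward_cluster(D, 3, signatures = sigs)
  cp <- condensed_profiles(prof, cl, D, n_medoids = 3)
  expect_true(all(c("cluster", "cgi_id", "coord", "beta", "region") %in% names(cp)))
  expect_true(all(cp$beta >= 0 & cp$beta <= 1))
  expect_lte(length(unique(cp$cgi_id[cp$cluster == "1"])), 3)
})
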