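mk_kernel <- function(ids, dmat) {
  structure(list(ids = ids,
                 similarity = 1 - `dimnames<-`(dmat, list(ids, ids))),
            class = "jaccard_kernel")
}

test_that("the kernel equals pairwise signature estimates", {
  profs <- random_profiles(40, dim = 450, seed = 61)
  sigs <- sign_all(profs)
  kern <- build_kernel(sigs)
  expect_true(isSymmetric(unname(kern$similarity)))
  expect_equal(unname(diag(kern$similarity)), rep(1, 40))
  spot <- withr::with_seed(62, t(replicate(100, sample.int(40, 2L))))
  for (r in seq_len(nrow(spot))) {
    i <- spot[r, 1]; j <- spot[r, 2]
    expect_identical(kern$similarity[i, j], estimate_jaccard(sigs[[i]], sigs[[j]]))
  }
  expect_error(build_kernel(sigs[1]), "at least 2")
})

test_that("identical and disjoint profiles bound the kernel entries", {
  dim <- 400L
  a <- structure(list(family_id = "a", coord = 0:39, weight = rep(1, 40), dim = dim),
                 class = "weighted_profile")
  b <- a; b$family_id <- "b"
  c_ <- structure(list(family_id = "c", coord = 200:239, weight = rep(1, 40), dim = dim),
                  class = "weighted_profile")
  kern <- build_kernel(sign_all(list(a, b, c_)))
  expect_equal(kern$similarity["a", "b"], 1.0)
  expect_lte(kern$similarity["a", "c"], 3 / sqrt(256))
})

test_that("UPGMA merges at half the average-linkage distance and cuts at the height", {
  dmat <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3)
  kern <- mk_kernel(c("A", "B", "C"), dmat)
  # merge heights: (A,B) at 1, then with C at 4
  cl3 <- upgma_clusters(kern, 3)
  expect_equal(unname(cl3$assignment[c("A", "B", "C")]), c(1L, 1L, 2L))
  expect_equal(cl3$n_clusters, 2L)
  cl5 <- upgma_clusters(kern, 5)
  expect_equal(cl5$n_clusters, 1L)
  # cutoff 0: all positive distances -> singletons
  expect_equal(upgma_clusters(kern, 0)$n_clusters, 3L)
  # non-symmetric matrix refused
  bad <- kern; bad$similarity[1, 2] <- 0.5
  expect_error(upgma_clusters(bad, 1), "symmetric")
})

test_that("clustering is invariant under kernel permutation", {
  profs <- random_profiles(30, dim = 450, seed = 63)
  kern <- build_kernel(sign_all(profs))
  perm <- withr::with_seed(64, sample.int(30))
  kern_p <- structure(list(ids = kern$ids[perm],
                           similarity = kern$similarity[perm, perm]),
                      class = "jaccard_kernel")
  for (cutoff in c(0.1, 0.35, 0.49)) {
    a <- upgma_clusters(kern, cutoff)$assignment
    b <- upgma_clusters(kern_p, cutoff)$assignment
    expect_identical(a, b[names(a)])
  }
})

test_that("binary Pearson behaves as the classic profile correlation", {
  expect_equal(binary_pearson(c(1, 0, 2, 0), c(3, 0, 1, 0)), 1.0)
  expect_equal(binary_pearson(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1.0)
  expect_error(binary_pearson(c(1, 1, 1, 1), c(1, 0, 1, 0)), "zero variance")
  expect_error(binary_pearson(c(1, 0), c(1, 0, 1)), "length")
})

test_that("occurrence metrics report Euclidean always, Pearson when defined", {
  m <- occurrence_metrics(c(2, 0), c(0, 2))
  expect_equal(m$euclidean, sqrt(8))
  expect_equal(m$pearson, -1.0)
  same <- occurrence_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$euclidean, 0)
  expect_equal(same$pearson, 1.0)
  const <- occurrence_metrics(c(1, 1), c(2, 2))
  expect_equal(const$euclidean, sqrt(2))
  expect_false(const$pearson_defined)
  expect_true(is.na(const$pearson))
})

test_that("ROC/AUC follows the rank (Mann-Whitney) convention", {
  # 3 of the 4 positive-negative comparisons are wins
  r <- roc_auc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  # perfect separation
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(3, 2, 1))$auc, 1.0)
  # label-independent scores at large n
  lab <- rep(c(TRUE, FALSE), 500)
  sc <- withr::with_seed(65, stats::runif(1000))
  expect_lt(abs(roc_auc(lab, sc)$auc - 0.5), 0.06)
  expect_error(roc_auc(c(TRUE, TRUE), c(1, 2)), "non-interacting")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  lab <- rep(c(TRUE, FALSE), each = 40)
  sc <- withr::with_seed(66, c(stats::rnorm(40, 1), stats::rnorm(40)))
  sc[5] <- sc[45]  # inject a tie across classes
  ours <- roc_auc(lab, sc)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("event-aware hash similarity ranks interactions at least as well as binary Pearson", {
  tax <- simulate_taxonomy(80, seed = 71)
  cfg <- sim_config(n_leaves = 80, coevolution_rho = 0.8, seed = 72)
  bench <- make_benchmark(tax, cfg, 200L)
  scheme <- phyloprof:::get_scheme(3L * tax$n_nodes, 256L, 1L)
  lab <- logical(0); hash_sc <- numeric(0); bin_sc <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(bench$pairs))) {
    fa <- bench$families[[bench$pairs$id_a[i]]]
    fb <- bench$families[[bench$pairs$id_b[i]]]
    pa <- build_profile(sim_family_event_tree(fa, tax), tax)
    pb <- build_profile(sim_family_event_tree(fb, tax), tax)
    # binary Pearson on the presence coordinates only (events stripped)
    bp <- tryCatch(binary_pearson(fa$present, fb$present), error = function(e) NA_real_)
    if (is.na(bp)) { dropped <- dropped + 1L; next }  # constant vector: drop, count
    lab <- c(lab, bench$pairs$label[i] == "interacting")
    bin_sc <- c(bin_sc, bp)
    hash_sc <- c(hash_sc, estimate_jaccard(sign_profile(pa, scheme = scheme),
                                           sign_profile(pb, scheme = scheme)))
  }
  expect_lt(dropped, nrow(bench$pairs) / 2)
  auc_hash <- roc_auc(lab, hash_sc)$auc
  auc_bin <- roc_auc(lab, bin_sc)$auc
  # designed advantage of event-aware profiles, allowing MinHash estimation noise
  expect_gte(auc_hash, auc_bin - 0.02)
})

test_that("network augmentation unions queries with their neighbours", {
  tax <- simulate_taxonomy(32, seed = 67)
  cfg <- sim_config(n_leaves = 32, seed = 68, n_families = 80)
  sigs <- sign_all(family_profiles(simulate_families(tax, cfg), tax))
  idx <- lsh_build(sigs, l = 8L)
  ids <- vapply(sigs, `[[`, character(1), "family_id")
  kern <- augment_network(idx, ids[1:4], k = 5L)
  expect_true(all(ids[1:4] %in% kern$ids))
  expect_lte(length(kern$ids), 4 * 6)  # dedup keeps it below queries x (k+1)
  expect_gte(length(kern$ids), 4)
  expect_true(isSymmetric(unname(kern$similarity)))
  expect_error(augment_network(idx, "nope", k = 2), "unknown query id")
})
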