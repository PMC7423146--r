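test_that("an empty index is valid and queries return nothing", {
  idx <- lsh_build(list(), l = 8L, n = 256L, scheme_seed = 1L, dim = 450L)
  profs <- random_profiles(1, dim = 450, seed = 41)
  q <- sign_profile(profs[[1]])
  expect_equal(nrow(lsh_query(idx, q, k = 5)), 0L)
})

test_that("every indexed signature retrieves itself with similarity 1", {
  profs <- random_profiles(60, dim = 450, seed = 42)
  sigs <- sign_all(profs)
  idx <- lsh_build(sigs, l = 8L)
  for (i in c(1L, 17L, 60L)) {
    res <- lsh_query(idx, sigs[[i]], k = 1L)
    expect_equal(res$family_id, sigs[[i]]$family_id)
    expect_equal(res$similarity, 1.0)
  }
  # k larger than the index returns everything, ranked
  res_all <- lsh_query(idx, sigs[[1]], k = 1000L)
  expect_equal(nrow(res_all), 60L)
  expect_equal(res_all$similarity, sort(res_all$similarity, decreasing = TRUE))
})

test_that("build validates parameters and duplicates", {
  profs <- random_profiles(3, dim = 450, seed = 43)
  sigs <- sign_all(profs)
  expect_error(lsh_build(sigs, l = 7L), "divisible")
  expect_error(lsh_build(c(sigs, sigs[1]), l = 8L), "duplicate family_id")
  mixed <- c(sigs[1:2], list(sign_profile(profs[[3]], n = 128L)))
  expect_error(lsh_build(mixed, l = 8L), "not comparable")
  idx <- lsh_build(sigs, l = 8L)
  expect_error(lsh_insert(idx, sigs[[1]]), "already indexed")
  expect_error(lsh_query(idx, sign_profile(profs[[1]], n = 128L), k = 1),
               "'n' differs")
})

test_that("incremental insertion answers queries exactly like batch build", {
  profs <- random_profiles(120, dim = 450, seed = 44)
  sigs <- sign_all(profs)
  batch <- lsh_build(sigs, l = 8L)
  inc <- lsh_build(list(), l = 8L, n = 256L, scheme_seed = 1L, dim = 450L)
  for (s in sigs) inc <- lsh_insert(inc, s)
  for (i in c(3L, 50L, 99L)) {
    rb <- lsh_query(batch, sigs[[i]], k = 10L)
    ri <- lsh_query(inc, sigs[[i]], k = 10L)
    attr(rb, "inspected") <- attr(ri, "inspected") <- NULL
    expect_identical(rb, ri)
  }
  # a freshly inserted signature is immediately retrievable
  extra <- sign_all(random_profiles(1, dim = 450, seed = 45))[[1]]
  extra$family_id <- "extra"
  inc2 <- lsh_insert(inc, extra)
  expect_equal(lsh_query(inc2, extra, k = 1L)$family_id, "extra")
})

test_that("the forest recovers the brute-force nearest neighbour", {
  tax <- simulate_taxonomy(48, seed = 46)
  cfg <- sim_config(n_leaves = 48, seed = 47, n_families = 600)
  fams <- simulate_families(tax, cfg)
  profs <- family_profiles(fams, tax)
  sigs <- sign_all(profs)
  idx <- lsh_build(sigs, l = 8L)
  mats <- phyloprof:::signature_matrices(sigs)
  hits <- 0L
  queries <- withr::with_seed(48, sample.int(length(sigs), 60L))
  for (qi in queries) {
    sims <- phyloprof:::row_similarities(mats$K, mats$T, mats$K[qi, ], mats$T[qi, ])
    sims[qi] <- -1  # exclude self
    best <- which.max(sims)
    res <- lsh_query(idx, sigs[[qi]], k = 11L)
    hits <- hits + (mats$ids[best] %in% res$family_id)
  }
  expect_gte(hits / length(queries), 0.9)
})

test_that("candidate inspections stay sub-linear for small k", {
  tax <- simulate_taxonomy(48, seed = 51)
  counts <- sapply(c(200L, 800L), function(nfam) {
    cfg <- sim_config(n_leaves = 48, seed = 52, n_families = nfam)
    sigs <- sign_all(family_profiles(simulate_families(tax, cfg), tax))
    idx <- lsh_build(sigs, l = 8L)
    queries <- withr::with_seed(53, sample.int(nfam, 25L))
    mean(sapply(queries, function(qi) {
      attr(lsh_query(idx, sigs[[qi]], k = 5L), "inspected")
    }))
  })
  # documented constant c = 6: inspected <= c * k * l * log2(size)
  bound <- 6 * 5 * 8 * log2(c(200, 800))
  expect_true(all(counts <= bound))
})
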