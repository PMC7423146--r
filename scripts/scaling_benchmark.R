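#!/usr/bin/env Rscript
# Timing comparison of three ways to find similar profiles, on synthetic
# binary vectors of length 100 (0 and 1 equiprobable):
#
#   explicit  all-vs-all exact Jaccard distance matrix + UPGMA clustering
#   svd       truncated SVD to 5 dimensions, normalised, Euclidean
#             distance matrix + UPGMA clustering
#   minhash   weighted MinHash signatures inserted into an LSH Forest,
#             then one top-10 query per profile
#
# The quadratic cost of the explicit routes against the near-linear cost of
# the sketch + forest route is the point; wall-clock numbers depend on the
# machine and are printed, not asserted.
#
#   Rscript scripts/scaling_benchmark.R [--sizes 100,250,500,1000] [--seed 1]

suppressPackageStartupMessages({
  library(optparse)
  library(phyloprof)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--sizes", type = "character", default = "100,250,500,1000"),
  make_option("--seed", type = "integer", default = 1L)
)))
sizes <- as.integer(strsplit(opts$sizes, ",")[[1L]])
len <- 100L

make_binary_profiles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- which(stats::runif(len) < 0.5)
    if (length(v) == 0L) v <- 1L
    weighted_profile(sprintf("b%05d", i), v - 1L, rep(1, length(v)), len)
  })
}

timings <- list()
for (n in sizes) {
  profs <- make_binary_profiles(n, opts$seed)

  t_explicit <- system.time({
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - exact_weighted_jaccard(profs[[i]], profs[[j]])
    }
    stats::hclust(stats::as.dist(d), method = "average")
  })[["elapsed"]]

  t_svd <- system.time({
    # dense matrix straight from the vectors (coordinate space = vector length)
    M <- do.call(rbind, lapply(profs, function(p) {
      v <- numeric(len); v[p$coord + 1L] <- p$weight; v
    }))
    sv <- svd(M, nu = 5L, nv = 5L)
    red <- sv$u %*% diag(sv$d[1:5])
    red <- red / pmax(sqrt(rowSums(red^2)), 1e-12)
    stats::hclust(stats::dist(red), method = "average")
  })[["elapsed"]]

  t_minhash <- system.time({
    scheme <- minhash_scheme(len, 256L, 1L)
    sigs <- lapply(profs, sign_profile, scheme = scheme)
    idx <- lsh_build(sigs, l = 8L)
    for (s in sigs[seq_len(min(50L, n))]) lsh_query(idx, s, k = 10L)
  })[["elapsed"]]

  timings[[length(timings) + 1L]] <-
    data.frame(n = n, explicit_jaccard_s = t_explicit, truncated_svd_s = t_svd,
               minhash_forest_s = t_minhash)
}
out <- do.call(rbind, timings)
print(out, row.names = FALSE)
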