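# Weighted MinHash by consistent weighted sampling (Ioffe-style).
#
# For every (hash sample i, coordinate k) the scheme draws r ~ Gamma(2,1),
# c ~ Gamma(2,1) and beta ~ U(0,1). For a profile with weight w_k > 0 on
# coordinate k:
#   t_k   = floor(log(w_k) / r + beta)
#   ln y  = r * (t_k - beta)
#   ln a  = ln c - ln y - r
# and sample i reports the (k, t_k) pair minimising ln a. Two profiles
# collide on sample i with probability equal to their weighted Jaccard
# similarity sum(min) / sum(max), which is what makes the match fraction of
# two signatures an unbiased Jaccard estimator.

# run expr with a private, restorable RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Create a weighted-MinHash sampling scheme
#'
#' The scheme fixes the random draws shared by every signature built with
#' the same `(dim, n, seed)` triple; signatures are only comparable when
#' these match. The default of 256 hash samples bounds the Jaccard
#' estimator's standard error by `sqrt(J(1-J)/256) <= 1/32`.
#'
#' @param dim Dense profile length (`3 * n_nodes` of the taxonomy).
#' @param n Number of hash samples per signature (default 256).
#' @param seed Integer scheme seed (default 1); recorded in every store.
#' @return A `minhash_scheme` object.
#' @export
minhash_scheme <- function(dim, n = 256L, seed = 1L) {
  stopifnot(dim >= 1L, n >= 1L)
  mats <- with_seed(seed, list(
    r    = matrix(stats::rgamma(n * dim, shape = 2, rate = 1), n, dim),
    ln_c = matrix(log(stats::rgamma(n * dim, shape = 2, rate = 1)), n, dim),
    beta = matrix(stats::runif(n * dim), n, dim)
  ))
  structure(list(dim = as.integer(dim), n = as.integer(n), seed = as.integer(seed),
                 r = mats$r, ln_c = mats$ln_c, beta = mats$beta),
            class = "minhash_scheme")
}

# schemes are expensive to draw; memoise the most recent few
.scheme_cache <- new.env(parent = emptyenv())

get_scheme <- function(dim, n, seed) {
  key <- paste(dim, n, seed, sep = "_")
  sc <- .scheme_cache[[key]]
  if (is.null(sc)) {
    if (length(ls(.scheme_cache)) >= 4L) rm(list = ls(.scheme_cache), envir = .scheme_cache)
    sc <- minhash_scheme(dim, n, seed)
    .scheme_cache[[key]] <- sc
  }
  sc
}

#' Sign a weighted profile
#'
#' Deterministically encodes a profile as a fixed-length weighted MinHash
#' signature under a sampling scheme. Independent samples of two signatures
#' agree with probability equal to the exact weighted Jaccard similarity of
#' the underlying profiles.
#'
#' @param p A non-empty `weighted_profile`.
#' @param n Number of hash samples (ignored when `scheme` is given).
#' @param scheme_seed Scheme seed (ignored when `scheme` is given).
#' @param scheme Optionally a prebuilt [minhash_scheme()] matching `p$dim`.
#' @return A `minhash_signature`: list with `family_id`, integer `k`
#'   (sampled 0-based coordinate per hash), numeric `t` (discretised weight
#'   level per hash), `n`, `dim` and `seed`.
#' @export
sign_profile <- function(p, n = 256L, scheme_seed = 1L, scheme = NULL) {
  stopifnot(inherits(p, "weighted_profile"))
  if (length(p$coord) == 0L) stop("cannot MinHash an empty profile", call. = FALSE)
  if (is.null(scheme)) scheme <- get_scheme(p$dim, n, scheme_seed)
  stopifnot(inherits(scheme, "minhash_scheme"))
  if (scheme$dim != p$dim) {
    stop("scheme dimension ", scheme$dim, " does not match profile dimension ",
         p$dim, call. = FALSE)
  }
  cols <- p$coord + 1L
  m <- length(cols)
  rs <- scheme$r[, cols, drop = FALSE]
  bs <- scheme$beta[, cols, drop = FALSE]
  lw <- matrix(log(p$weight), nrow = scheme$n, ncol = m, byrow = TRUE)
  tm <- floor(lw / rs + bs)
  ln_a <- scheme$ln_c[, cols, drop = FALSE] - rs * (tm - bs) - rs
  j <- max.col(-ln_a, ties.method = "first")
  pick <- cbind(seq_len(scheme$n), j)
  structure(list(
    family_id = p$family_id,
    k = p$coord[j],
    t = tm[pick],
    n = scheme$n, dim = scheme$dim, seed = scheme$seed
  ), class = "minhash_signature")
}

check_comparable <- function(a, b) {
  for (f in c("n", "seed", "dim")) {
    if (!identical(a[[f]], b[[f]])) {
      stop("signatures not comparable: '", f, "' differs (", a[[f]], " vs ", b[[f]], ")",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Estimate Jaccard similarity from two signatures
#'
#' The fraction of hash positions at which the two signatures carry the same
#' (coordinate, level) sample — an unbiased estimator of the weighted
#' Jaccard similarity of the underlying profiles, computed in O(n).
#'
#' @param a,b `minhash_signature`s built under the same scheme.
#' @return A number in `[0, 1]`, always a multiple of `1/n`.
#' @export
estimate_jaccard <- function(a, b) {
  stopifnot(inherits(a, "minhash_signature"), inherits(b, "minhash_signature"))
  check_comparable(a, b)
  mean(a$k == b$k & a$t == b$t)
}

#' Exact weighted Jaccard similarity of two profiles
#'
#' `sum_i min(a_i, b_i) / sum_i max(a_i, b_i)` over the shared coordinate
#' space — the brute-force oracle the MinHash estimator approximates.
#'
#' @param a,b `weighted_profile`s over the same coordinate space.
#' @return A number in `[0, 1]`.
#' @export
exact_weighted_jaccard <- function(a, b) {
  stopifnot(inherits(a, "weighted_profile"), inherits(b, "weighted_profile"))
  if (a$dim != b$dim) stop("profiles live in different coordinate spaces", call. = FALSE)
  if (length(a$coord) == 0L && length(b$coord) == 0L) {
    stop("weighted Jaccard of two empty profiles is undefined", call. = FALSE)
  }
  u <- union(a$coord, b$coord)
  av <- numeric(length(u)); av[match(a$coord, u)] <- a$weight
  bv <- numeric(length(u)); bv[match(b$coord, u)] <- b$weight
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

# stack a list of comparable signatures into integer matrices (families x n)
signature_matrices <- function(sigs) {
  stopifnot(length(sigs) >= 1L)
  for (s in sigs) stopifnot(inherits(s, "minhash_signature"))
  if (length(sigs) > 1L) for (s in sigs[-1L]) check_comparable(sigs[[1L]], s)
  ids <- vapply(sigs, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) {
    stop("duplicate family_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  n <- sigs[[1L]]$n
  K <- do.call(rbind, lapply(sigs, `[[`, "k"))
  T_ <- do.call(rbind, lapply(sigs, `[[`, "t"))
  list(ids = ids, K = K, T = T_,
       n = n, dim = sigs[[1L]]$dim, seed = sigs[[1L]]$seed)
}

# similarity of one signature (qk, qt) against rows of K/T
row_similarities <- function(K, T_, qk, qt, rows = seq_len(nrow(K))) {
  if (length(rows) == 0L) return(numeric(0))
  n <- ncol(K)
  QK <- matrix(qk, nrow = length(rows), ncol = n, byrow = TRUE)
  QT <- matrix(qt, nrow = length(rows), ncol = n, byrow = TRUE)
  rowMeans(K[rows, , drop = FALSE] == QK & T_[rows, , drop = FALSE] == QT)
}
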