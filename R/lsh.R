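# LSH Forest over weighted-MinHash signatures.
#
# The n hash samples of each signature are split into l contiguous slices of
# depth d = n / l, one per prefix tree. Within a tree, a signature's path is
# the sequence of its d (coordinate, level) sample tokens; two signatures
# share a prefix of length j when their first j tokens agree, which for
# independent samples happens with probability J^j. Prefix identity is
# tracked with a per-depth rolling hash (mod 2^26) kept in one numeric
# matrix per tree, so lookups are vectorised and insertion is append-only;
# hash collisions can only ever add spurious candidates, which the
# full-signature re-ranking step discards.

# Token/rolling-hash constants. The modulus is prime (largest below 2^26)
# and the token mixes k and t multiplicatively so that low-entropy inputs
# (e.g. t = 0 everywhere under uniform weights) still spread over the whole
# hash range; every intermediate stays exactly representable in a double.
TOKEN_A <- 2654435761   # Knuth multiplicative constant
TOKEN_B <- 40503
TOKEN_TMOD <- 65536
PREFIX_MULT <- 48271    # Lehmer multiplier
PREFIX_MOD <- 67108859  # prime; PREFIX_MOD * PREFIX_MULT < 2^53

hash_tokens <- function(k, t) {
  (k * TOKEN_A + (t %% TOKEN_TMOD) * TOKEN_B) %% PREFIX_MOD
}

# rolling prefix hashes for one signature: l x d matrix
prefix_hashes <- function(k, t, l, d) {
  tok <- hash_tokens(k, t)
  H <- matrix(0, nrow = l, ncol = d)
  for (tr in seq_len(l)) {
    h <- 0
    off <- (tr - 1L) * d
    for (j in seq_len(d)) {
      h <- (h * PREFIX_MULT + tok[off + j]) %% PREFIX_MOD
      H[tr, j] <- h
    }
  }
  H
}

#' Build an LSH Forest index over signatures
#'
#' @param sigs List of comparable `minhash_signature`s with unique family
#'   ids (may be empty, giving a valid empty index).
#' @param l Number of prefix trees (default 8); must divide the signature
#'   length `n`, so each tree hashes a slice of depth `n / l`.
#' @param n,scheme_seed,dim Signature parameters; required only when `sigs`
#'   is empty, otherwise taken from the signatures.
#' @return An `lsh_forest` object supporting [lsh_insert()] and
#'   [lsh_query()].
#' @export
lsh_build <- function(sigs, l = 8L, n = 256L, scheme_seed = 1L, dim = NULL) {
  l <- as.integer(l)
  if (length(sigs) == 0L) {
    if (is.null(dim)) stop("dim is required to build an empty index", call. = FALSE)
    if (n %% l != 0L) stop("n (", n, ") must be divisible by l (", l, ")", call. = FALSE)
    idx <- structure(list(
      params = list(n = as.integer(n), l = l, d = as.integer(n %/% l),
                    seed = as.integer(scheme_seed), dim = as.integer(dim)),
      ids = character(0),
      K = matrix(0L, 0L, n), T = matrix(0, 0L, n),
      H = replicate(l, matrix(0, 0L, n %/% l), simplify = FALSE)
    ), class = "lsh_forest")
    return(idx)
  }
  mats <- signature_matrices(sigs)
  if (mats$n %% l != 0L) {
    stop("n (", mats$n, ") must be divisible by l (", l, ")", call. = FALSE)
  }
  idx <- lsh_build(list(), l = l, n = mats$n, scheme_seed = mats$seed, dim = mats$dim)
  d <- idx$params$d
  tok <- hash_tokens(mats$K, mats$T)
  H <- vector("list", l)
  for (tr in seq_len(l)) {
    off <- (tr - 1L) * d
    Ht <- matrix(0, nrow = nrow(tok), ncol = d)
    h <- rep(0, nrow(tok))
    for (j in seq_len(d)) {
      h <- (h * PREFIX_MULT + tok[, off + j]) %% PREFIX_MOD
      Ht[, j] <- h
    }
    H[[tr]] <- Ht
  }
  idx$ids <- mats$ids
  idx$K <- mats$K
  storage.mode(idx$K) <- "integer"
  idx$T <- mats$T
  idx$H <- H
  idx
}

#' @export
print.lsh_forest <- function(x, ...) {
  cat(sprintf("<lsh_forest> %d signatures, %d trees of depth %d (n = %d)\n",
              length(x$ids), x$params$l, x$params$d, x$params$n))
  invisible(x)
}

check_query_comparable <- function(idx, s) {
  if (!identical(as.integer(s$n), idx$params$n)) {
    stop("signature not comparable with index: 'n' differs (", s$n, " vs ",
         idx$params$n, ")", call. = FALSE)
  }
  if (!identical(as.integer(s$seed), idx$params$seed)) {
    stop("signature not comparable with index: 'scheme_seed' differs (", s$seed,
         " vs ", idx$params$seed, ")", call. = FALSE)
  }
  if (!identical(as.integer(s$dim), idx$params$dim)) {
    stop("signature not comparable with index: 'dim' differs (", s$dim, " vs ",
         idx$params$dim, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Insert a signature into an LSH Forest
#'
#' The signature is immediately retrievable by self-query; batch build is
#' defined as repeated insertion, so incremental and batch indexes over the
#' same signatures answer queries identically.
#'
#' @param idx An `lsh_forest`.
#' @param s A comparable `minhash_signature` whose family id is not yet
#'   indexed.
#' @return The updated index.
#' @export
lsh_insert <- function(idx, s) {
  stopifnot(inherits(idx, "lsh_forest"), inherits(s, "minhash_signature"))
  check_query_comparable(idx, s)
  if (s$family_id %in% idx$ids) {
    stop("family_id '", s$family_id, "' already indexed", call. = FALSE)
  }
  Hq <- prefix_hashes(s$k, s$t, idx$params$l, idx$params$d)
  idx$ids <- c(idx$ids, s$family_id)
  idx$K <- rbind(idx$K, as.integer(s$k))
  idx$T <- rbind(idx$T, as.numeric(s$t))
  for (tr in seq_len(idx$params$l)) idx$H[[tr]] <- rbind(idx$H[[tr]], Hq[tr, ])
  idx
}

#' Query an LSH Forest for the k most similar signatures
#'
#' Candidates are gathered by descending shared-prefix length across all
#' trees until at least `oversample * k` distinct families are found (or,
#' failing `k`, the whole index is used). Candidates are then re-ranked by
#' the full-signature Jaccard estimate against the query; the forest is a
#' candidate generator only. Oversampling matters because prefix collisions
#' favour near-duplicates: descending a few levels further past the first
#' `k` candidates lets moderately similar true neighbours surface before
#' re-ranking.
#'
#' @param idx An `lsh_forest`.
#' @param q A comparable `minhash_signature` (need not be indexed).
#' @param k Number of neighbours requested.
#' @param oversample Candidate-budget multiplier (default 8).
#' @return A data frame (`rank`, `family_id`, `similarity`) of at most `k`
#'   rows, similarity descending, ties broken by insertion order. The number
#'   of candidate inspections performed is attached as attribute
#'   `"inspected"`.
#' @export
lsh_query <- function(idx, q, k = 10L, oversample = 8L) {
  stopifnot(inherits(idx, "lsh_forest"), inherits(q, "minhash_signature"),
            k >= 1L, oversample >= 1L)
  check_query_comparable(idx, q)
  N <- length(idx$ids)
  if (N == 0L) {
    out <- data.frame(rank = integer(0), family_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
    attr(out, "inspected") <- 0L
    return(out)
  }
  Hq <- prefix_hashes(q$k, q$t, idx$params$l, idx$params$d)
  budget <- k * oversample
  cand <- integer(0)
  inspected <- 0L
  for (depth in rev(seq_len(idx$params$d))) {
    for (tr in seq_len(idx$params$l)) {
      m <- which(idx$H[[tr]][, depth] == Hq[tr, depth])
      inspected <- inspected + length(m)
      cand <- union(cand, m)
    }
    if (length(cand) >= budget) break
  }
  if (length(cand) < k) cand <- seq_len(N)  # exhaustion: empty prefix matches all
  cand <- sort(cand)
  sims <- row_similarities(idx$K, idx$T, q$k, q$t, rows = cand)
  ord <- order(-sims, cand)
  take <- utils::head(ord, k)
  out <- data.frame(rank = seq_along(take), family_id = idx$ids[cand[take]],
                    similarity = sims[take], stringsAsFactors = FALSE)
  attr(out, "inspected") <- inspected
  out
}

#' Rebuild an LSH Forest from a signature store
#'
#' Signatures on disk are the source of truth; the forest structure itself
#' is never serialised.
#'
#' @param store A [read_signature_store()] result or a store directory path.
#' @param l Number of prefix trees.
#' @return An `lsh_forest` over all stored signatures.
#' @export
lsh_from_store <- function(store, l = 8L) {
  if (is.character(store)) store <- read_signature_store(store)
  sigs <- store_signatures(store)
  lsh_build(sigs, l = l)
}

#' Write ranked query results as TSV
#'
#' @param res A [lsh_query()] result.
#' @param path Output TSV path.
#' @return Invisibly, `res`.
#' @export
write_query_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
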