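# Plain-text signature store: one directory holding
#   signatures.tsv       family_id, k_1..k_n, t_1..t_n   (families x 2n matrix)
#   meta.json            n, scheme_seed, dim, packing version, taxonomy checksum
#   taxonomy.nwk         the taxonomy the coordinates refer to
#   taxonomy_order.tsv   (index, name, weight) master-order sidecar
# Signatures are the source of truth: the LSH forest is rebuilt from the
# store on load rather than serialised.

PACKING_VERSION <- "3n+c/v1"

# FNV-1a 32-bit over a string; doubles only, all intermediates exact:
# the XOR touches just the low byte, the multiply is split 16/16 bits.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + (h %% 65536) * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

taxonomy_checksum <- function(tax) {
  fnv1a32(paste(tax$name, format(tax$weight, digits = 15), collapse = ";"))
}

#' Write a signature store
#'
#' Persists signatures together with every parameter needed to compare
#' against them later: hash count, scheme seed, coordinate-packing version
#' and a checksum plus full sidecar of the taxonomy order.
#'
#' @param sigs List of comparable `minhash_signature`s.
#' @param tax The taxonomy the profiles were built on.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_signature_store <- function(sigs, tax, dir) {
  stopifnot(inherits(tax, "taxonomy"))
  mats <- signature_matrices(sigs)
  if (mats$dim != 3L * tax$n_nodes) {
    stop("signature dimension does not match taxonomy", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(family_id = mats$ids, stringsAsFactors = FALSE)
  K <- mats$K; T_ <- mats$T
  colnames(K) <- paste0("k_", seq_len(ncol(K)))
  colnames(T_) <- paste0("t_", seq_len(ncol(T_)))
  df <- cbind(df, as.data.frame(K), as.data.frame(T_))
  utils::write.table(df, file.path(dir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_taxonomy(tax, file.path(dir, "taxonomy.nwk"),
                 file.path(dir, "taxonomy_order.tsv"))
  meta <- list(n = mats$n, scheme_seed = mats$seed, dim = mats$dim,
               packing = PACKING_VERSION, n_families = length(mats$ids),
               taxonomy_checksum = taxonomy_checksum(tax))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a signature store
#'
#' @param dir Store directory written by [write_signature_store()].
#' @return List with `ids`, integer matrices `K` and `T` (families x n),
#'   `meta`, and the reloaded `taxonomy`.
#' @export
read_signature_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  tax <- load_taxonomy(paste(readLines(file.path(dir, "taxonomy.nwk")), collapse = ""))
  ord <- utils::read.table(file.path(dir, "taxonomy_order.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tax <- set_weights(tax, stats::setNames(ord$weight, ord$name))
  if (!identical(taxonomy_checksum(tax), meta$taxonomy_checksum)) {
    stop("taxonomy checksum mismatch: store is inconsistent", call. = FALSE)
  }
  df <- utils::read.table(file.path(dir, "signatures.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(family_id = "character"))
  n <- meta$n
  K <- as.matrix(df[, paste0("k_", seq_len(n)), drop = FALSE])
  T_ <- as.matrix(df[, paste0("t_", seq_len(n)), drop = FALSE])
  dimnames(K) <- NULL; dimnames(T_) <- NULL
  list(ids = df$family_id, K = K, T = T_, meta = meta, taxonomy = tax)
}

# reconstruct signature objects from store matrices
store_signatures <- function(store, ids = store$ids) {
  idx <- match(ids, store$ids)
  if (anyNA(idx)) {
    stop("unknown family id(s): ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  lapply(idx, function(i) structure(list(
    family_id = store$ids[i], k = as.integer(store$K[i, ]), t = as.numeric(store$T[i, ]),
    n = as.integer(store$meta$n), dim = as.integer(store$meta$dim),
    seed = as.integer(store$meta$scheme_seed)
  ), class = "minhash_signature"))
}
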