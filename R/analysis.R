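#' All-vs-all Jaccard kernel over signatures
#'
#' Entry (i, j) is the MinHash Jaccard estimate between signatures i and j;
#' the matrix is symmetric with unit diagonal. The corresponding distance
#' kernel is `1 - similarity`.
#'
#' @param sigs List of at least two comparable `minhash_signature`s.
#' @return A `jaccard_kernel`: list with `ids` and the `similarity` matrix
#'   (dimnames set to the family ids).
#' @export
build_kernel <- function(sigs) {
  if (length(sigs) < 2L) stop("a kernel needs at least 2 signatures", call. = FALSE)
  mats <- signature_matrices(sigs)
  kernel_from_matrices(mats$K, mats$T, mats$ids)
}

kernel_from_matrices <- function(K, T_, ids) {
  N <- length(ids)
  sim <- matrix(1, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N - 1L)) {
    rows <- (i + 1L):N
    s <- row_similarities(K, T_, K[i, ], T_[i, ], rows = rows)
    sim[i, rows] <- s
    sim[rows, i] <- s
  }
  structure(list(ids = ids, similarity = sim), class = "jaccard_kernel")
}

#' @export
print.jaccard_kernel <- function(x, ...) {
  cat(sprintf("<jaccard_kernel> %d x %d families\n", length(x$ids), length(x$ids)))
  invisible(x)
}

#' UPGMA clustering of a Jaccard kernel at a flat height cutoff
#'
#' Average-linkage (UPGMA) hierarchical clustering of the distance matrix
#' `1 - similarity`. Merge heights follow the ultrametric convention: the
#' height of a merge node is half the average-linkage distance between the
#' two clusters it joins (so two items at distance 2 merge at height 1).
#' Flat clusters are cut where the merge height exceeds `cutoff`: families
#' stay together exactly when they merge at height `<= cutoff`. Families are
#' canonically ordered by id before clustering, so the result is invariant
#' under row/column permutation of the kernel, and cluster labels are
#' numbered by each cluster's lexicographically smallest member.
#'
#' @param kern A `jaccard_kernel` (or any symmetric similarity kernel with
#'   the same structure).
#' @param cutoff Non-negative merge-height cutoff.
#' @return A `cluster_assignment`: list with `assignment` (named integer
#'   vector, family id -> cluster label), `cutoff` and `n_clusters`.
#' @export
upgma_clusters <- function(kern, cutoff) {
  stopifnot(inherits(kern, "jaccard_kernel"), is.numeric(cutoff), cutoff >= 0)
  sim <- kern$similarity
  if (!isSymmetric(unname(sim), tol = 1e-12)) {
    stop("kernel matrix must be symmetric", call. = FALSE)
  }
  ord <- order(kern$ids)
  ids <- kern$ids[ord]
  d <- stats::as.dist(1 - sim[ord, ord, drop = FALSE])
  hc <- stats::hclust(d, method = "average")
  # cophenetic distance <= 2 * cutoff  <=>  ultrametric merge height <= cutoff
  labels_raw <- stats::cutree(hc, h = 2 * cutoff)
  first_member <- tapply(seq_along(ids), labels_raw, min)
  relabel <- match(labels_raw, labels_raw[sort(as.integer(first_member))])
  assignment <- stats::setNames(relabel, ids)
  structure(list(assignment = assignment, cutoff = cutoff,
                 n_clusters = max(relabel)), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d families in %d clusters (cutoff %.4g)\n",
              length(x$assignment), x$n_clusters, x$cutoff))
  invisible(x)
}

#' Pearson correlation of binarised profiles
#'
#' The classic binary phylogenetic-profile metric: any positive weight is
#' set to 1 and the Pearson correlation of the two 0/1 vectors is returned.
#' A constant vector has no defined correlation and is an explicit error, so
#' benchmarks must drop (and count) such pairs rather than silently score
#' them.
#'
#' @param a,b Dense numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
binary_pearson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  ab <- as.numeric(a > 0)
  bb <- as.numeric(b > 0)
  if (stats::var(ab) == 0 || stats::var(bb) == 0) {
    stop("zero variance: binary Pearson undefined for constant vectors", call. = FALSE)
  }
  stats::cor(ab, bb)
}

#' Occurrence-profile baseline metrics
#'
#' Distances over copy-number (occurrence) vectors: plain Euclidean distance
#' and Pearson correlation. When either vector is constant the correlation
#' is undefined; the Euclidean distance is still returned and
#' `pearson_defined` is set to `FALSE`.
#'
#' @param a,b Copy-number vectors of equal length (0 where absent).
#' @return List with `euclidean`, `pearson` (`NA` when undefined) and
#'   `pearson_defined`.
#' @export
occurrence_metrics <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  eu <- sqrt(sum((a - b)^2))
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(list(euclidean = eu, pearson = NA_real_, pearson_defined = FALSE))
  }
  list(euclidean = eu, pearson = stats::cor(a, b), pearson_defined = TRUE)
}

#' ROC curve and AUC for a scored benchmark
#'
#' Positives are interacting pairs and higher scores mean more likely
#' positive (negate a distance before calling). The ROC curve sweeps the
#' score threshold over the unique observed values; the AUC is computed by
#' the rank (Mann-Whitney) formula, so tied scores contribute half wins —
#' identical to the trapezoid rule on the tie-grouped curve.
#'
#' @param labels Logical vector (or factor/character coerced via
#'   `== "interacting"`), `TRUE` for interacting pairs.
#' @param scores Numeric scores, one per pair.
#' @return List with `curve` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels) == "interacting"
  }
  stopifnot(is.logical(labels), length(labels) == length(scores))
  if (anyNA(labels) || anyNA(scores)) stop("labels/scores contain NA", call. = FALSE)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) {
    stop("both interacting and non-interacting pairs are required", call. = FALSE)
  }
  r <- rank(scores)  # midpoint ranks handle ties
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos))
  list(curve = curve, auc = auc)
}

#' Augment a query set with its nearest neighbours and build their kernel
#'
#' Runs each query family against the forest, takes the union of the queries
#' and their top-k hits (deduplicated, queries first) and returns the
#' all-vs-all Jaccard kernel over that set — the cluster-ready input for
#' module discovery around a seed network.
#'
#' @param idx An `lsh_forest` whose indexed signatures include all
#'   `query_ids`.
#' @param query_ids Character vector of indexed family ids.
#' @param k Neighbours retrieved per query.
#' @return A `jaccard_kernel` over queries and retrieved families.
#' @export
augment_network <- function(idx, query_ids, k = 10L) {
  stopifnot(inherits(idx, "lsh_forest"))
  pos <- match(query_ids, idx$ids)
  if (anyNA(pos)) {
    stop("unknown query id(s): ", paste(query_ids[is.na(pos)], collapse = ", "),
         call. = FALSE)
  }
  hits <- character(0)
  for (p in pos) {
    q <- structure(list(family_id = idx$ids[p], k = as.integer(idx$K[p, ]),
                        t = as.numeric(idx$T[p, ]), n = idx$params$n,
                        dim = idx$params$dim, seed = idx$params$seed),
                   class = "minhash_signature")
    hits <- c(hits, lsh_query(idx, q, k = k)$family_id)
  }
  members <- unique(c(idx$ids[pos], hits))
  rows <- match(members, idx$ids)
  kernel_from_matrices(idx$K[rows, , drop = FALSE], idx$T[rows, , drop = FALSE], members)
}

#' Write a kernel as a TSV matrix
#' @param kern A `jaccard_kernel`.
#' @param path Output path.
#' @return Invisibly, `kern`.
#' @export
write_kernel_tsv <- function(kern, path) {
  m <- as.data.frame(kern$similarity)
  utils::write.table(cbind(family_id = kern$ids, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(kern)
}

#' Write a cluster assignment as TSV
#' @param cl A `cluster_assignment`.
#' @param path Output path.
#' @return Invisibly, `cl`.
#' @export
write_clusters_tsv <- function(cl, path) {
  df <- data.frame(family_id = names(cl$assignment), cluster = unname(cl$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cl)
}

#' Write a ROC curve (TSV) and AUC summary (JSON)
#' @param roc A [roc_auc()] result.
#' @param curve_path,summary_path Output paths.
#' @return Invisibly, `roc`.
#' @export
write_roc <- function(roc, curve_path, summary_path) {
  utils::write.table(roc$curve, curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc), summary_path, auto_unbox = TRUE, digits = NA)
  invisible(roc)
}
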