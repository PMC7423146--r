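#' Reference species taxonomy
#'
#' A `taxonomy` is the coordinate system of every profile built by this
#' package: a rooted species tree in which *every* node, leaf or internal,
#' carries a unique non-empty name and a fixed integer index. Indices follow
#' a preorder traversal of the tree as written in the newick source (parent
#' before children, children in written order), so re-loading the same text
#' always yields the same indexing and signatures built against it remain
#' comparable across sessions.
#'
#' @param newick_text Character scalar holding one rooted newick tree. All
#'   internal nodes must be labelled; labels must be unique.
#'
#' @return An object of class `taxonomy`: a list with elements `name`
#'   (character, preorder), `parent` (integer, `NA` at the root), `children`
#'   (list of integer vectors), `is_leaf` (logical), `weight` (numeric,
#'   default 1 everywhere) and `n_nodes`.
#'
#' @examples
#' tax <- load_taxonomy("((A,B)AB,C)Root;")
#' tax$name      # "Root" "AB" "A" "B" "C"
#' tax$n_nodes   # 5
#' @export
load_taxonomy <- function(newick_text) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  phy <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) stop("malformed newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(phy)) stop("malformed newick: could not parse tree text", call. = FALSE)
  if (inherits(phy, "multiPhylo")) stop("expected a single tree, got several", call. = FALSE)

  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  if (is.null(phy$node.label) || length(phy$node.label) != nint) {
    stop("validation error: all internal nodes must be labelled", call. = FALSE)
  }
  labels <- c(phy$tip.label, phy$node.label)
  bad <- which(is.na(labels) | labels == "")
  if (length(bad) > 0L) {
    stop("validation error: every node must be labelled; unlabelled node(s) at ape id(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    stop("validation error: duplicate label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  phy <- stats::reorder(phy, "cladewise")  # edges in preorder, written child order
  root_ape <- ntip + 1L
  preorder_ape <- c(root_ape, phy$edge[, 2L])  # DFS visit order of all nodes
  n <- ntip + nint
  stopifnot(length(preorder_ape) == n)
  idx_of_ape <- integer(n)
  idx_of_ape[preorder_ape] <- seq_len(n)

  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (e in seq_len(nrow(phy$edge))) {
    p <- idx_of_ape[phy$edge[e, 1L]]
    c_ <- idx_of_ape[phy$edge[e, 2L]]
    parent[c_] <- p
    children[[p]] <- c(children[[p]], c_)
  }

  structure(list(
    name     = labels[preorder_ape],
    parent   = parent,
    children = children,
    is_leaf  = vapply(children, function(x) length(x) == 0L, logical(1)),
    weight   = rep(1.0, n),
    n_nodes  = n
  ), class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes (%d leaves), root '%s'\n",
              x$n_nodes, sum(x$is_leaf), x$name[1L]))
  invisible(x)
}

# index of each name; error mentions unknown names
tax_index <- function(tax, names) {
  i <- match(names, tax$name)
  if (anyNA(i)) {
    stop("unknown taxonomy node name(s): ", paste(names[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

# all node indices in the subtree rooted at i (including i), preorder-sorted
tax_subtree <- function(tax, i) {
  out <- integer(0)
  stack <- i
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(tax$children[[v]]))
  }
  sort(out)
}

# ancestors of i up to (and including) stop_at; excludes i itself
tax_ancestors_until <- function(tax, i, stop_at) {
  out <- integer(0)
  v <- tax$parent[i]
  while (!is.na(v)) {
    out <- c(out, v)
    if (!is.na(stop_at) && v == stop_at) return(out)
    v <- tax$parent[v]
  }
  if (is.na(stop_at)) return(out)
  stop("node '", tax$name[stop_at], "' is not an ancestor of '", tax$name[i], "'",
       call. = FALSE)
}

# number of leaves under each node (vector over all nodes)
tax_leaf_counts <- function(tax) {
  cnt <- as.integer(tax$is_leaf)
  for (v in rev(seq_len(tax$n_nodes))) {   # reverse preorder = children first
    p <- tax$parent[v]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[v]
  }
  cnt
}

#' Prune a taxonomy to a set of leaves
#'
#' Keeps exactly the named leaves and every ancestor of a kept leaf. Internal
#' nodes left with a single surviving child are retained, not collapsed:
#' taxonomic levels keep their identity so that profiles built before and
#' after pruning stay interpretable. Indices are recomputed but preserve the
#' original relative preorder.
#'
#' @param tax A `taxonomy`.
#' @param keep Character vector of leaf names to keep (non-empty subset of
#'   the taxonomy's leaves).
#' @return A new `taxonomy`.
#' @examples
#' tax <- load_taxonomy("((A,B)AB,C)Root;")
#' prune_to_leaves(tax, c("A", "C"))$name  # "Root" "AB" "A" "C"
#' @export
prune_to_leaves <- function(tax, keep) {
  stopifnot(inherits(tax, "taxonomy"))
  if (length(keep) == 0L) stop("keep must name at least one leaf", call. = FALSE)
  keep <- unique(as.character(keep))
  leaf_names <- tax$name[tax$is_leaf]
  unknown <- setdiff(keep, leaf_names)
  if (length(unknown) > 0L) {
    stop("unknown leaf name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep_idx <- tax_index(tax, keep)
  mark <- rep(FALSE, tax$n_nodes)
  for (i in keep_idx) {
    mark[i] <- TRUE
    v <- tax$parent[i]
    while (!is.na(v) && !mark[v]) {
      mark[v] <- TRUE
      v <- tax$parent[v]
    }
  }
  old <- which(mark)                    # ascending = original preorder
  new_of_old <- integer(tax$n_nodes)
  new_of_old[old] <- seq_along(old)
  parent <- ifelse(is.na(tax$parent[old]), NA_integer_, new_of_old[tax$parent[old]])
  children <- lapply(old, function(i) new_of_old[tax$children[[i]][mark[tax$children[[i]]]]])
  structure(list(
    name     = tax$name[old],
    parent   = as.integer(parent),
    children = children,
    is_leaf  = vapply(children, function(x) length(x) == 0L, logical(1)),
    weight   = tax$weight[old],
    n_nodes  = length(old)
  ), class = "taxonomy")
}

#' Assign per-node weights
#'
#' Weights scale a node's contribution to every profile subsequently built on
#' this taxonomy: the Jaccard score between profiles is more heavily
#' influenced by nodes with a higher weight, and weight 0 removes a node's
#' coordinates from profiles entirely (a clade filter). Unnamed nodes keep
#' their current weight (default 1).
#'
#' @param tax A `taxonomy`.
#' @param weights Named numeric vector (possibly empty); names are taxonomy
#'   node names, values finite and non-negative.
#' @return The updated `taxonomy`.
#' @export
set_weights <- function(tax, weights) {
  stopifnot(inherits(tax, "taxonomy"))
  if (length(weights) == 0L) return(tax)
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be a named vector", call. = FALSE)
  }
  w <- as.numeric(weights)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("validation error: weights must be finite and >= 0", call. = FALSE)
  }
  idx <- tax_index(tax, names(weights))
  tax$weight[idx] <- w
  tax
}

#' Serialise a taxonomy to newick
#'
#' @param tax A `taxonomy`.
#' @return A newick string (no branch lengths), terminated by `;`.
#' @export
taxonomy_to_newick <- function(tax) {
  stopifnot(inherits(tax, "taxonomy"))
  rec <- function(i) {
    ch <- tax$children[[i]]
    if (length(ch) == 0L) return(tax$name[i])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", tax$name[i])
  }
  paste0(rec(1L), ";")
}

#' Write a taxonomy and its order sidecar
#'
#' Persists the tree (newick) together with the master node order the
#' coordinate system depends on: a TSV of (index, name, weight), index
#' 0-based to match profile coordinate packing. Every built signature store
#' carries this sidecar so indexes remain portable.
#'
#' @param tax A `taxonomy`.
#' @param newick_path,order_path Output file paths.
#' @return Invisibly, the order data frame.
#' @export
write_taxonomy <- function(tax, newick_path, order_path) {
  writeLines(taxonomy_to_newick(tax), newick_path)
  ord <- data.frame(index = seq_len(tax$n_nodes) - 1L, name = tax$name,
                    weight = tax$weight, stringsAsFactors = FALSE)
  utils::write.table(ord, order_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ord)
}
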