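#' Flatten an event tree into a weighted multiset profile
#'
#' The profile coordinate space has `3 * n_nodes` columns: coordinate id
#' `3 * node_index + category` (0-based node index; category 0 = presence,
#' 1 = loss, 2 = duplication). A node contributes its taxonomy weight to the
#' coordinate of each event category it carries; nodes with weight 0 are
#' filtered out entirely. Presence, loss and duplication are encoded as
#' binary occurrences scaled by the node weight — copy numbers beyond the
#' duplication flag stay on the event tree for the occurrence baselines and
#' are deliberately not encoded here.
#'
#' @param ev An `event_tree` built on `tax`.
#' @param tax The taxonomy defining the coordinate space.
#' @return An object of class `weighted_profile`: list with `family_id`,
#'   `coord` (0-based integer coordinate ids, strictly increasing), `weight`
#'   (positive), and `dim = 3 * n_nodes`.
#' @export
build_profile <- function(ev, tax) {
  stopifnot(inherits(ev, "event_tree"), inherits(tax, "taxonomy"))
  n <- tax$n_nodes
  if (length(ev$present) != n) {
    stop("event tree and taxonomy node sets do not match", call. = FALSE)
  }
  w <- tax$weight
  mk <- function(flags, category) {
    idx <- which(flags & w > 0)
    list(coord = 3L * (idx - 1L) + category, weight = w[idx])
  }
  parts <- list(mk(ev$present, 0L), mk(ev$lost, 1L), mk(ev$duplicated, 2L))
  coord <- c(parts[[1]]$coord, parts[[2]]$coord, parts[[3]]$coord)
  weight <- c(parts[[1]]$weight, parts[[2]]$weight, parts[[3]]$weight)
  if (length(coord) == 0L) {
    stop("degenerate profile: family '", ev$family_id,
         "' has no weighted coordinates", call. = FALSE)
  }
  ord <- order(coord)
  structure(list(
    family_id = ev$family_id,
    coord = coord[ord],
    weight = weight[ord],
    dim = 3L * n
  ), class = "weighted_profile")
}

#' @export
print.weighted_profile <- function(x, ...) {
  cat(sprintf("<weighted_profile> %s: %d of %d coordinates\n",
              x$family_id, length(x$coord), x$dim))
  invisible(x)
}

#' Construct a weighted profile directly
#'
#' Builds a `weighted_profile` from explicit sparse coordinates — the
#' entry point for profile-like data that does not come from an event tree
#' (e.g. plain binary presence/absence vectors).
#'
#' @param family_id Identifier.
#' @param coord Integer vector of 0-based coordinate ids (unique).
#' @param weight Positive weights, one per coordinate.
#' @param dim Dense length of the coordinate space.
#' @return A `weighted_profile`.
#' @export
weighted_profile <- function(family_id, coord, weight, dim) {
  coord <- as.integer(coord)
  if (anyDuplicated(coord)) stop("duplicate coordinates", call. = FALSE)
  if (length(coord) != length(weight)) {
    stop("coord and weight lengths differ", call. = FALSE)
  }
  if (length(coord) > 0L && (min(coord) < 0L || max(coord) >= dim)) {
    stop("coordinates out of range [0, dim)", call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weights must be finite and > 0", call. = FALSE)
  }
  ord <- order(coord)
  structure(list(family_id = as.character(family_id), coord = coord[ord],
                 weight = as.numeric(weight)[ord], dim = as.integer(dim)),
            class = "weighted_profile")
}

#' Expand a sparse profile to its dense weight vector
#'
#' @param p A `weighted_profile`.
#' @param tax The taxonomy defining the coordinate space.
#' @return Numeric vector of length `3 * n_nodes` (zeros where no entry).
#' @export
profile_to_dense <- function(p, tax) {
  stopifnot(inherits(p, "weighted_profile"), inherits(tax, "taxonomy"))
  dim <- 3L * tax$n_nodes
  if (length(p$coord) > 0L && (max(p$coord) >= dim || min(p$coord) < 0L)) {
    stop("profile coordinate out of range for this taxonomy", call. = FALSE)
  }
  v <- numeric(dim)
  v[p$coord + 1L] <- p$weight
  v
}

#' Export profiles as a tidy TSV
#'
#' One row per non-zero coordinate: family id, coordinate id, node name,
#' event category and weight — the inspection format for profiles.
#'
#' @param profiles List of `weighted_profile`s.
#' @param tax The taxonomy they were built on.
#' @param path Output TSV path.
#' @return Invisibly, the exported data frame.
#' @export
write_profiles_tsv <- function(profiles, tax, path) {
  cats <- c("presence", "loss", "duplication")
  rows <- lapply(profiles, function(p) {
    node <- p$coord %/% 3L + 1L
    data.frame(family_id = p$family_id, coordinate = p$coord,
               node_name = tax$name[node], category = cats[p$coord %% 3L + 1L],
               weight = p$weight, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
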