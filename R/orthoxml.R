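#' Parse OrthoXML into hierarchical orthologous groups
#'
#' Reads a standard OrthoXML document (nested `orthologGroup` /
#' `paralogGroup` / `geneRef` elements plus the species/gene header) and
#' resolves it against a reference taxonomy. Each top-level `orthologGroup`
#' becomes one family. Taxonomic ranges are taken from
#' `<property name="TaxRange" value="..."/>` elements; an `orthologGroup`
#' must carry one, a `paralogGroup` may omit it, in which case it inherits
#' the level of the nearest enclosing `orthologGroup`. Node names are
#' matched case-sensitively against taxonomy node names, species against
#' taxonomy leaves.
#'
#' @param xml_text OrthoXML document as a single character string, or a file
#'   path to one.
#' @param tax A [load_taxonomy()] taxonomy.
#' @return A list of `hog_family` objects, each a list with `family_id`,
#'   `root_level` (taxonomy node name), `group` (nested group structure) and
#'   `genes` (data frame of `gene_id`, `species`).
#' @export
parse_orthoxml <- function(xml_text, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop("OrthoXML parse error: ", conditionMessage(e), call. = FALSE)
  )
  xml2::xml_ns_strip(doc)

  leaf_names <- tax$name[tax$is_leaf]

  # species/gene header: gene internal id -> species
  sp_nodes <- xml2::xml_find_all(doc, ".//species")
  gene_ids <- character(0)
  gene_species <- character(0)
  gene_labels <- character(0)
  for (sp in sp_nodes) {
    sname <- xml2::xml_attr(sp, "name")
    if (is.na(sname) || !(sname %in% leaf_names)) {
      stop("unresolvable species name in OrthoXML header: '", sname, "'", call. = FALSE)
    }
    gs <- xml2::xml_find_all(sp, ".//gene")
    gene_ids <- c(gene_ids, xml2::xml_attr(gs, "id"))
    gene_labels <- c(gene_labels, xml2::xml_attr(gs, "geneId"))
    gene_species <- c(gene_species, rep(sname, length(gs)))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s) in OrthoXML: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "), call. = FALSE)
  }
  names(gene_species) <- gene_ids
  names(gene_labels) <- gene_ids

  get_level <- function(node) {
    props <- xml2::xml_find_all(node, "./property[@name='TaxRange']")
    if (length(props) == 0L) return(NA_character_)
    xml2::xml_attr(props[[1L]], "value")
  }

  is_anc_or_eq <- function(anc, node) {
    v <- node
    while (!is.na(v)) {
      if (v == anc) return(TRUE)
      v <- tax$parent[v]
    }
    FALSE
  }

  parse_group <- function(node, inherited_level) {
    type <- xml2::xml_name(node)
    if (type == "geneRef") {
      gid <- xml2::xml_attr(node, "id")
      sp <- gene_species[[gid]]
      if (is.null(sp) || is.na(sp)) {
        stop("geneRef id '", gid, "' not declared in species header", call. = FALSE)
      }
      return(list(type = "gene", gene_id = gid, species = sp,
                  level_idx = tax_index(tax, sp)))
    }
    if (!type %in% c("orthologGroup", "paralogGroup")) return(NULL)
    lvl <- get_level(node)
    if (is.na(lvl)) {
      if (type == "orthologGroup") {
        stop("orthologGroup without a TaxRange annotation", call. = FALSE)
      }
      lvl_idx <- inherited_level
    } else {
      lvl_idx <- tax_index(tax, lvl)
    }
    if (!is.na(inherited_level) && !is_anc_or_eq(inherited_level, lvl_idx)) {
      stop("group nesting violates taxonomy ancestry: level '", tax$name[lvl_idx],
           "' is not within '", tax$name[inherited_level], "'", call. = FALSE)
    }
    kids <- xml2::xml_children(node)
    parsed <- list()
    for (kid in kids) {
      pk <- parse_group(kid, lvl_idx)
      if (!is.null(pk)) parsed[[length(parsed) + 1L]] <- pk
    }
    list(type = if (type == "orthologGroup") "ortholog" else "paralog",
         level_idx = lvl_idx, children = parsed)
  }

  groups_node <- xml2::xml_find_first(doc, ".//groups")
  tops <- if (inherits(groups_node, "xml_missing")) list() else
    xml2::xml_find_all(groups_node, "./orthologGroup")

  fams <- vector("list", length(tops))
  for (i in seq_along(tops)) {
    g <- parse_group(tops[[i]], NA_integer_)
    fid <- xml2::xml_attr(tops[[i]], "id")
    if (is.na(fid)) fid <- sprintf("fam%04d", i)
    collect_genes <- function(gr) {
      if (gr$type == "gene") {
        return(data.frame(gene_id = gr$gene_id, species = gr$species,
                          stringsAsFactors = FALSE))
      }
      do.call(rbind, lapply(gr$children, collect_genes))
    }
    genes <- collect_genes(g)
    fams[[i]] <- structure(list(
      family_id = fid,
      root_level = tax$name[g$level_idx],
      group = g,
      genes = genes
    ), class = "hog_family")
  }
  fams
}

#' @export
print.hog_family <- function(x, ...) {
  cat(sprintf("<hog_family> %s: root level '%s', %d genes\n",
              x$family_id, x$root_level, nrow(x$genes)))
  invisible(x)
}

# Lineage counting over the group tree. Returns an integer vector over all
# taxonomy nodes: the number of distinct gene lineages of the family at each
# node. Speciation (orthologGroup) keeps a single lineage from its level down
# to the point where each child takes over; duplication (paralogGroup at
# level L) contributes one lineage per copy at L and along the path to each
# copy's own level, so nested duplications compound multiplicatively.
count_lineages <- function(group, tax) {
  n <- tax$n_nodes
  rec <- function(g) {
    cnt <- integer(n)
    if (g$type == "gene") {
      cnt[g$level_idx] <- 1L
      return(cnt)
    }
    L <- g$level_idx
    fill <- integer(0)
    for (child in g$children) {
      cnt <- cnt + rec(child)
      Li <- child$level_idx
      path <- if (Li == L) integer(0) else c(tax_ancestors_until(tax, Li, L))
      if (g$type == "paralog") {
        cnt[path] <- cnt[path] + 1L
      } else {
        fill <- union(fill, c(path, L))
      }
    }
    if (g$type == "ortholog") {
      zero <- fill[cnt[fill] == 0L]
      cnt[zero] <- 1L
    }
    cnt
  }
  rec(group)
}

#' Infer the event-labelled tree profile of a family
#'
#' Reconciles a parsed family against the taxonomy to annotate every node
#' with presence, loss, duplication and copy number — the "enhanced
#' phylogeny" of the family. The gene family gains at its root level; a node
#' is present when its subtree (within the root level's clade) retains at
#' least one extant gene; a loss is recorded only at the topmost node of
#' each maximal extinct subtree under a present parent (one event per loss);
#' a duplication is flagged exactly where the lineage count exceeds the
#' parent's (the parent of the root level counts as 1).
#'
#' @param fam A `hog_family` from [parse_orthoxml()].
#' @param tax The taxonomy the family was parsed against.
#' @return An object of class `event_tree`: list with `family_id`,
#'   `root_level`, and per-node logical vectors `present`, `lost`,
#'   `duplicated` plus integer `copy_number` (0 where absent).
#' @export
infer_event_tree <- function(fam, tax) {
  stopifnot(inherits(fam, "hog_family"), inherits(tax, "taxonomy"))
  root_idx <- tax_index(tax, fam$root_level)
  cnt <- count_lineages(fam$group, tax)

  sub <- tax_subtree(tax, root_idx)
  present <- rep(FALSE, tax$n_nodes)
  present[sub] <- cnt[sub] > 0L

  lost <- rep(FALSE, tax$n_nodes)
  cand <- setdiff(sub, root_idx)
  lost[cand] <- !present[cand] & present[tax$parent[cand]]

  duplicated_ <- rep(FALSE, tax$n_nodes)
  for (i in sub[present[sub]]) {
    parent_cn <- if (i == root_idx) 1L else cnt[tax$parent[i]]
    if (cnt[i] > parent_cn) duplicated_[i] <- TRUE
  }
  cn <- cnt
  cn[!present] <- 0L

  structure(list(
    family_id = fam$family_id,
    root_level = fam$root_level,
    present = present,
    lost = lost,
    duplicated = duplicated_,
    copy_number = cn
  ), class = "event_tree")
}

#' @export
print.event_tree <- function(x, ...) {
  cat(sprintf("<event_tree> %s: gain at '%s', %d present, %d losses, %d duplications\n",
              x$family_id, x$root_level, sum(x$present), sum(x$lost), sum(x$duplicated)))
  invisible(x)
}

#' Per-node copy-number (occurrence) vector of an event tree
#'
#' The occurrence-profile variant used by the baseline metrics: the family's
#' copy number at every taxonomy node, 0 where absent.
#'
#' @param ev An `event_tree`.
#' @return Integer vector of length `n_nodes`.
#' @export
event_occurrence <- function(ev) {
  stopifnot(inherits(ev, "event_tree"))
  ev$copy_number
}
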