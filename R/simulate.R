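# Synthetic gene-family evolution on a species tree.
#
# Families evolve by a branch-wise Bernoulli process: a family gains at one
# taxonomy node, and on every branch below it is independently lost (the
# whole subtree is pruned for all gene copies) or duplicated (every lineage
# crossing the branch doubles, so copy numbers are powers of two). Logged
# ground truth is canonicalised to the observable events: losses are lifted
# to the topmost node of each maximal extinct subtree and duplications in
# fully lost subtrees are dropped, which is exactly the convention the
# event-inference stage reports. Families whose every leaf goes extinct are
# rejected and resampled, with the rejection count reported.

#' Simulation configuration
#'
#' Defaults describe a moderately volatile eukaryote-like regime: families
#' arise uniformly at any internal node with at least `gain_min_leaves`
#' descendant species (very small clades carry almost no profiling signal),
#' lose each branch with probability 0.15 and duplicate with probability
#' 0.05; co-evolving partners copy 80% of each other's losses.
#'
#' @param n_leaves Number of species in the simulated taxonomy.
#' @param loss_rate,dup_rate Per-branch loss/duplication probabilities in
#'   `[0, 1]` (`loss_rate = 1` is rejected: no family could survive).
#' @param gain_node_sampler `"internal"` (uniform over internal nodes with
#'   `>= gain_min_leaves` leaves, the default), `"root"`, or `"uniform"`
#'   (any node, including leaves).
#' @param gain_min_leaves Minimum subtree size for `"internal"` gains.
#' @param coevolution_rho Probability that a partner family copies a given
#'   loss event of its mate.
#' @param n_families Default family count for batch helpers.
#' @param seed Integer seed from which all batch randomness flows.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves = 100L, loss_rate = 0.15, dup_rate = 0.05,
                       gain_node_sampler = c("internal", "root", "uniform"),
                       gain_min_leaves = 4L, coevolution_rho = 0.8,
                       n_families = 100L, seed = 1L) {
  gain_node_sampler <- match.arg(gain_node_sampler)
  stopifnot(n_leaves >= 2L, n_families >= 1L)
  for (r in c(loss_rate, dup_rate, coevolution_rho)) {
    if (!is.finite(r) || r < 0 || r > 1) {
      stop("rates must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_leaves = as.integer(n_leaves), loss_rate = loss_rate,
                 dup_rate = dup_rate, gain_node_sampler = gain_node_sampler,
                 gain_min_leaves = as.integer(gain_min_leaves),
                 coevolution_rho = coevolution_rho,
                 n_families = as.integer(n_families), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random species taxonomy
#'
#' Builds a rooted binary tree by uniform coalescent-style joins of the
#' leaf set, with unique auto-generated names for leaves (`s...`) and
#' internal nodes (`n...`, in join order). Deterministic for a given seed.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return A `taxonomy` with `2 * n_leaves - 1` nodes.
#' @export
simulate_taxonomy <- function(n_leaves, seed = 1L) {
  if (n_leaves < 2L) stop("n_leaves must be >= 2", call. = FALSE)
  wd <- max(3L, nchar(as.character(2L * n_leaves)))
  fmt <- paste0("%0", wd, "d")
  newick <- with_seed(seed, {
    active <- sprintf(paste0("s", fmt), seq_len(n_leaves))
    join <- 0L
    while (length(active) > 1L) {
      pick <- sample.int(length(active), 2L)
      join <- join + 1L
      merged <- sprintf(paste0("(%s,%s)n", fmt), active[pick[1L]], active[pick[2L]], join)
      active <- c(active[-pick], merged)
    }
    paste0(active, ";")
  })
  load_taxonomy(newick)
}

# draw a gain node index under the configured sampler
sample_gain_node <- function(tax, cfg, leaf_counts) {
  cand <- switch(cfg$gain_node_sampler,
    root = 1L,
    uniform = seq_len(tax$n_nodes),
    internal = {
      thr <- min(cfg$gain_min_leaves, sum(tax$is_leaf))
      which(!tax$is_leaf & leaf_counts >= thr)
    })
  if (length(cand) == 0L) cand <- 1L
  cand[sample.int(length(cand), 1L)]
}

# one forward pass below `gain`; returns raw per-branch events + copy numbers
branch_process <- function(tax, gain, loss_prob_fun, dup_rate) {
  cn <- numeric(tax$n_nodes)
  losses <- integer(0)
  dups <- integer(0)
  cn[gain] <- 1
  stack <- list(gain)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (ch in tax$children[[v]]) {
      if (stats::runif(1) < loss_prob_fun(ch)) {
        losses <- c(losses, ch)
      } else {
        mult <- cn[v]
        if (stats::runif(1) < dup_rate) {
          dups <- c(dups, ch)
          mult <- 2 * mult
        }
        cn[ch] <- mult
        stack[[length(stack) + 1L]] <- ch
      }
    }
  }
  list(cn = cn, losses = losses, dups = dups)
}

# lift events to their observable form (see file header)
canonicalize_events <- function(tax, gain, raw) {
  sub <- tax_subtree(tax, gain)
  has_extant <- rep(FALSE, tax$n_nodes)
  extant_leaf <- tax$is_leaf & raw$cn > 0
  for (v in rev(sub)) {
    has_extant[v] <- extant_leaf[v] || any(has_extant[tax$children[[v]]])
  }
  present <- has_extant
  if (!present[gain]) return(NULL)  # extinct family
  cand <- setdiff(sub, gain)
  losses <- cand[!present[cand] & present[tax$parent[cand]]]
  dups <- raw$dups[present[raw$dups]]
  cn <- raw$cn
  cn[!present] <- 0
  list(present = present, losses = losses, dups = dups, cn = cn)
}

new_sim_family <- function(tax, family_id, gain, canon, raw, rejections) {
  genes <- canon$cn[tax$is_leaf & canon$present]
  names(genes) <- tax$name[tax$is_leaf & canon$present]
  structure(list(
    family_id = family_id,
    gain = tax$name[gain],
    losses = sort(tax$name[canon$losses]),
    duplications = sort(tax$name[canon$dups]),
    genes = genes,
    present = canon$present,
    copy_number = canon$cn,
    raw_losses = tax$name[raw$losses],
    rejections = rejections
  ), class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %s: gain '%s', %d losses, %d duplications, %d genes\n",
              x$family_id, x$gain, length(x$losses), length(x$duplications),
              sum(x$genes)))
  invisible(x)
}

#' Simulate one gene family
#'
#' Draws a gain node, then applies the branch-wise loss/duplication process
#' below it. Extinct outcomes are rejected and resampled; the number of
#' rejections is recorded on the returned family (`$rejections`).
#' Randomness is drawn from R's current RNG stream: seed the stream (or use
#' the batch helpers, which seed it from `cfg$seed`) for reproducibility.
#'
#' @param tax A `taxonomy`.
#' @param cfg A [sim_config()].
#' @param family_id Identifier for the family.
#' @return A `sim_family` with logged ground truth: `gain`, `losses`,
#'   `duplications` (canonical observable events, as node names), `genes`
#'   (extant copy count per species), plus the full per-node `present` /
#'   `copy_number` vectors.
#' @export
simulate_family <- function(tax, cfg, family_id = "fam1") {
  stopifnot(inherits(tax, "taxonomy"), inherits(cfg, "sim_config"))
  if (cfg$loss_rate >= 1) stop("loss_rate = 1: no family can survive", call. = FALSE)
  leaf_counts <- tax_leaf_counts(tax)
  rejections <- 0L
  repeat {
    gain <- sample_gain_node(tax, cfg, leaf_counts)
    raw <- branch_process(tax, gain, function(ch) cfg$loss_rate, cfg$dup_rate)
    canon <- canonicalize_events(tax, gain, raw)
    if (!is.null(canon)) {
      return(new_sim_family(tax, family_id, gain, canon, raw, rejections))
    }
    rejections <- rejections + 1L
  }
}

#' Simulate a batch of families under one seed
#'
#' @param tax A `taxonomy`.
#' @param cfg A [sim_config()]; `cfg$n_families` and `cfg$seed` drive the
#'   batch.
#' @param id_prefix Prefix for generated family ids.
#' @return List of `sim_family` objects; total rejection count in attribute
#'   `"rejections"`.
#' @export
simulate_families <- function(tax, cfg, id_prefix = "fam") {
  with_seed(cfg$seed, {
    fams <- lapply(seq_len(cfg$n_families), function(i) {
      simulate_family(tax, cfg, family_id = sprintf("%s%05d", id_prefix, i))
    })
    attr(fams, "rejections") <- sum(vapply(fams, `[[`, integer(1), "rejections"))
    fams
  })
}

#' Simulate a co-evolving family pair
#'
#' Family A evolves freely. Family B shares A's gain node; on each branch it
#' copies A's loss with probability `coevolution_rho` and additionally loses
#' independently at rate `loss_rate * (1 - coevolution_rho)` (branches A
#' never reached are subject only to the independent rate). Duplications
#' remain independent. At `rho = 1` the partners' loss sets are identical.
#'
#' @param tax A `taxonomy`.
#' @param cfg A [sim_config()].
#' @param id_a,id_b Family ids for the pair.
#' @return List of two `sim_family`s (`a`, `b`); B records which of its raw
#'   losses were copied from A in attribute fields `raw_losses` /
#'   `copied_losses`.
#' @export
simulate_coevolving_pair <- function(tax, cfg, id_a = "famA", id_b = "famB") {
  a <- simulate_family(tax, cfg, family_id = id_a)
  gain <- tax_index(tax, a$gain)
  p_priv <- cfg$loss_rate * (1 - cfg$coevolution_rho)
  a_lost <- tax$name %in% a$raw_losses
  rejections <- 0L
  repeat {
    loss_prob <- function(ch) {
      if (a_lost[ch]) 1 - (1 - cfg$coevolution_rho) * (1 - p_priv) else p_priv
    }
    raw <- branch_process(tax, gain, loss_prob, cfg$dup_rate)
    canon <- canonicalize_events(tax, gain, raw)
    if (!is.null(canon)) {
      b <- new_sim_family(tax, id_b, gain, canon, raw, rejections)
      b$copied_losses <- intersect(b$raw_losses, a$raw_losses)
      return(list(a = a, b = b))
    }
    rejections <- rejections + 1L
  }
}

#' Build a balanced labelled benchmark
#'
#' Half the pairs are co-evolving partners (label `interacting`), half are
#' independently simulated family pairs (label `non-interacting`) — the
#' synthetic analogue of complex-membership benchmarks where negatives mix
#' proteins from different complexes. Balanced by construction; an odd
#' `n_pairs` is an error.
#'
#' @param tax A `taxonomy`.
#' @param cfg A [sim_config()]; `cfg$seed` drives all randomness.
#' @param n_pairs Even number of labelled pairs.
#' @return List with `pairs` (data frame `id_a`, `id_b`, `label`) and
#'   `families` (named list of `sim_family`s).
#' @export
make_benchmark <- function(tax, cfg, n_pairs) {
  stopifnot(inherits(tax, "taxonomy"), inherits(cfg, "sim_config"), n_pairs >= 2L)
  if (n_pairs %% 2L != 0L) {
    stop("n_pairs must be even to keep the benchmark balanced", call. = FALSE)
  }
  with_seed(cfg$seed, {
    half <- n_pairs %/% 2L
    fams <- list()
    rows <- vector("list", n_pairs)
    for (i in seq_len(half)) {
      ida <- sprintf("pos%04da", i); idb <- sprintf("pos%04db", i)
      pr <- simulate_coevolving_pair(tax, cfg, ida, idb)
      fams[[ida]] <- pr$a; fams[[idb]] <- pr$b
      rows[[i]] <- data.frame(id_a = ida, id_b = idb, label = "interacting",
                              stringsAsFactors = FALSE)
    }
    for (i in seq_len(half)) {
      ida <- sprintf("neg%04da", i); idb <- sprintf("neg%04db", i)
      fams[[ida]] <- simulate_family(tax, cfg, ida)
      fams[[idb]] <- simulate_family(tax, cfg, idb)
      rows[[half + i]] <- data.frame(id_a = ida, id_b = idb, label = "non-interacting",
                                     stringsAsFactors = FALSE)
    }
    list(pairs = do.call(rbind, rows), families = fams)
  })
}

#' Convert a simulated family to an event tree
#'
#' The simulator's logged ground truth in `event_tree` form, built directly
#' from the forward process (no OrthoXML involved) — the oracle side of the
#' round-trip recovery check.
#'
#' @param fam A `sim_family`.
#' @param tax The taxonomy it was simulated on.
#' @return An `event_tree`.
#' @export
sim_family_event_tree <- function(fam, tax) {
  stopifnot(inherits(fam, "sim_family"), inherits(tax, "taxonomy"))
  lost <- rep(FALSE, tax$n_nodes)
  lost[tax_index(tax, fam$losses)] <- TRUE
  dup <- rep(FALSE, tax$n_nodes)
  if (length(fam$duplications) > 0L) dup[tax_index(tax, fam$duplications)] <- TRUE
  structure(list(
    family_id = fam$family_id,
    root_level = fam$gain,
    present = fam$present,
    lost = lost,
    duplicated = dup,
    copy_number = as.integer(fam$copy_number)
  ), class = "event_tree")
}

#' Serialise simulated families as OrthoXML
#'
#' Writes a standard-conformant OrthoXML document (species/gene header plus
#' nested ortholog/paralog groups with TaxRange annotations) such that
#' parsing it back and re-inferring events recovers every family's logged
#' gain, losses and duplications exactly. Deterministic given the families.
#'
#' @param families List of `sim_family`s (each with at least one gene).
#' @param tax The taxonomy they were simulated on.
#' @param path Optional output file.
#' @return The OrthoXML document as a character string (invisibly when
#'   `path` is given).
#' @export
write_orthoxml <- function(families, tax, path = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  for (f in families) {
    stopifnot(inherits(f, "sim_family"))
    if (sum(f$genes) == 0) {
      stop("family '", f$family_id, "' has no genes", call. = FALSE)
    }
  }
  gene_counter <- 0L
  species_genes <- list()  # species name -> data.frame(id, label)

  fam_xml <- character(length(families))
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    gain <- tax_index(tax, fam$gain)
    present <- fam$present
    dup <- rep(FALSE, tax$n_nodes)
    if (length(fam$duplications) > 0L) dup[tax_index(tax, fam$duplications)] <- TRUE

    new_gene <- function(sp_idx) {
      gene_counter <<- gene_counter + 1L
      sp <- tax$name[sp_idx]
      label <- sprintf("%s_%s_g%d", fam$family_id, sp, gene_counter)
      df <- species_genes[[sp]]
      species_genes[[sp]] <<- rbind(df, data.frame(id = gene_counter, label = label,
                                                   stringsAsFactors = FALSE))
      sprintf('<geneRef id="%d"/>', gene_counter)
    }
    # one gene lineage at node v and everything below it
    copy_rep <- function(v) {
      if (tax$is_leaf[v]) return(new_gene(v))
      surv <- tax$children[[v]][present[tax$children[[v]]]]
      if (length(surv) == 1L) return(element(surv))
      kids <- vapply(surv, element, character(1))
      sprintf('<orthologGroup><property name="TaxRange" value="%s"/>%s</orthologGroup>',
              tax$name[v], paste(kids, collapse = ""))
    }
    # a present child branch, wrapping the duplication at it (if any)
    element <- function(ch) {
      if (dup[ch]) {
        sprintf('<paralogGroup><property name="TaxRange" value="%s"/>%s%s</paralogGroup>',
                tax$name[ch], copy_rep(ch), copy_rep(ch))
      } else {
        copy_rep(ch)
      }
    }
    body <- if (dup[gain]) {
      # duplication at the gain level itself: two copies under the root group
      sprintf('<paralogGroup><property name="TaxRange" value="%s"/>%s%s</paralogGroup>',
              tax$name[gain], copy_rep(gain), copy_rep(gain))
    } else {
      copy_rep(gain)
    }
    if (!grepl(sprintf('^<orthologGroup><property name="TaxRange" value="%s"/>', tax$name[gain]),
               body)) {
      body <- sprintf('<orthologGroup><property name="TaxRange" value="%s"/>%s</orthologGroup>',
                      tax$name[gain], body)
    }
    fam_xml[fi] <- sub("^<orthologGroup>",
                       sprintf('<orthologGroup id="%s">', fam$family_id), body)
  }

  sp_order <- tax$name[tax$is_leaf]
  sp_order <- sp_order[sp_order %in% names(species_genes)]
  sp_xml <- vapply(sp_order, function(sp) {
    df <- species_genes[[sp]]
    genes <- paste(sprintf('<gene id="%d" geneId="%s"/>', df$id, df$label), collapse = "")
    sprintf('<species name="%s" NCBITaxId="0"><database name="phyloprof-sim" version="1"><genes>%s</genes></database></species>',
            sp, genes)
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="phyloprof" originVersion="0.1">\n',
    paste(sp_xml, collapse = "\n"), "\n",
    "<groups>\n", paste(fam_xml, collapse = "\n"), "\n</groups>\n",
    "</orthoXML>\n"
  )
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Write simulated ground truth as TSV
#'
#' One row per family: gain node and comma-separated loss and duplication
#' node lists.
#'
#' @param families List of `sim_family`s.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_ground_truth_tsv <- function(families, path) {
  df <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, gain = f$gain,
               losses = paste(f$losses, collapse = ","),
               duplications = paste(f$duplications, collapse = ","),
               n_genes = sum(f$genes), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a labelled benchmark pair table as TSV
#' @param pairs Data frame `id_a`, `id_b`, `label` from [make_benchmark()].
#' @param path Output TSV path.
#' @return Invisibly, `pairs`.
#' @export
write_benchmark_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairs)
}
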