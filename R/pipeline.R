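# Pipeline entry points tying the stages together: build a signature store
# from taxonomy + OrthoXML, query it, cluster it, and emit simulation
# fixture bundles. Every command writes a JSON manifest with its resolved
# configuration and counts, sufficient to reproduce the run byte-for-byte.

read_weights_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "weight") %in% colnames(df)))
  stats::setNames(df$weight, df$name)
}

write_manifest <- function(dir, command, config, counts) {
  manifest <- list(command = command, package = "phyloprof",
                   version = as.character(utils::packageVersion("phyloprof")),
                   config = config, counts = counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build a signature store from taxonomy and OrthoXML inputs
#'
#' Runs the full profiling pipeline: load (and optionally weight) the
#' taxonomy, parse each OrthoXML document, infer event trees, build
#' weighted profiles, sign them, and persist the signature store together
#' with the taxonomy order sidecar and a run manifest. Re-running with the
#' same inputs produces identical store contents. On any stage error the
#' partial store is removed and the error is propagated with the offending
#' family's id attached.
#'
#' @param taxonomy_file Newick file with named internal nodes.
#' @param orthoxml_files Character vector of OrthoXML paths.
#' @param out_dir Store directory to create.
#' @param n_hashes Signature length (default 256).
#' @param n_trees LSH trees `l` (default 8); must divide `n_hashes`
#'   (recorded in the manifest for query time).
#' @param scheme_seed MinHash scheme seed (default 1).
#' @param weights_file Optional TSV (`name`, `weight`) of taxon weights.
#' @return Invisibly, `out_dir`.
#' @export
run_build <- function(taxonomy_file, orthoxml_files, out_dir,
                      n_hashes = 256L, n_trees = 8L, scheme_seed = 1L,
                      weights_file = NULL) {
  if (n_hashes %% n_trees != 0L) {
    stop("n_hashes must be divisible by n_trees", call. = FALSE)
  }
  created <- !dir.exists(out_dir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  tax <- load_taxonomy(paste(readLines(taxonomy_file), collapse = ""))
  if (!is.null(weights_file)) tax <- set_weights(tax, read_weights_tsv(weights_file))

  scheme <- get_scheme(3L * tax$n_nodes, n_hashes, scheme_seed)
  sigs <- list()
  for (xf in orthoxml_files) {
    fams <- parse_orthoxml(paste(readLines(xf), collapse = "\n"), tax)
    for (fam in fams) {
      sig <- tryCatch({
        ev <- infer_event_tree(fam, tax)
        sign_profile(build_profile(ev, tax), scheme = scheme)
      }, error = function(e) {
        stop("family '", fam$family_id, "' (", xf, "): ", conditionMessage(e),
             call. = FALSE)
      })
      sigs[[length(sigs) + 1L]] <- sig
    }
  }
  if (length(sigs) == 0L) stop("no families found in input", call. = FALSE)
  write_signature_store(sigs, tax, out_dir)
  write_manifest(out_dir, "build",
                 config = list(taxonomy_file = taxonomy_file,
                               orthoxml_files = orthoxml_files,
                               n_hashes = n_hashes, n_trees = n_trees,
                               scheme_seed = scheme_seed,
                               weights_file = weights_file,
                               packing = PACKING_VERSION),
                 counts = list(n_families = length(sigs), n_nodes = tax$n_nodes,
                               taxonomy_checksum = taxonomy_checksum(tax)))
  ok <- TRUE
  invisible(out_dir)
}

#' Query a signature store for co-evolving families
#'
#' Rebuilds the LSH forest from the store and retrieves the top-k most
#' similar families to an indexed query family.
#'
#' @param store_dir A [run_build()] store directory.
#' @param family_id Indexed family to query with.
#' @param k Number of neighbours.
#' @param n_trees LSH trees used to rebuild the forest.
#' @param out Optional TSV output path (`rank`, `family_id`, `similarity`).
#' @return The ranked result data frame.
#' @export
run_query <- function(store_dir, family_id, k = 10L, n_trees = 8L, out = NULL) {
  store <- read_signature_store(store_dir)
  idx <- lsh_from_store(store, l = n_trees)
  q <- store_signatures(store, family_id)[[1L]]
  res <- lsh_query(idx, q, k = k)
  if (!is.null(out)) write_query_tsv(res, out)
  res
}

#' Kernel and UPGMA clusters for a set of stored families
#'
#' Builds the all-vs-all Jaccard kernel over the named families (all stored
#' families by default) and cuts UPGMA clusters at the given height.
#'
#' @param store_dir A [run_build()] store directory.
#' @param ids Family ids (default: all in the store; at least 2).
#' @param cutoff UPGMA merge-height cutoff.
#' @param out_prefix Optional path prefix; writes `<prefix>_kernel.tsv` and
#'   `<prefix>_clusters.tsv`.
#' @return List with `kernel` and `clusters`.
#' @export
run_kernel_cluster <- function(store_dir, ids = NULL, cutoff = 0.35,
                               out_prefix = NULL) {
  store <- read_signature_store(store_dir)
  if (is.null(ids)) ids <- store$ids
  sigs <- store_signatures(store, ids)
  kern <- build_kernel(sigs)
  cl <- upgma_clusters(kern, cutoff)
  if (!is.null(out_prefix)) {
    write_kernel_tsv(kern, paste0(out_prefix, "_kernel.tsv"))
    write_clusters_tsv(cl, paste0(out_prefix, "_clusters.tsv"))
  }
  list(kernel = kern, clusters = cl)
}

#' Simulate a fixture bundle
#'
#' Generates a taxonomy and a batch of families (plus, optionally, a
#' labelled benchmark) and writes the standard-format bundle: newick
#' taxonomy, OrthoXML families, ground-truth TSV, benchmark TSV and a
#' manifest. Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param n_benchmark_pairs If > 0, also write a balanced benchmark.
#' @return Invisibly, a list with the taxonomy, families and benchmark.
#' @export
run_simulate <- function(cfg, out_dir, n_benchmark_pairs = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tax <- simulate_taxonomy(cfg$n_leaves, seed = cfg$seed)
  fams <- simulate_families(tax, cfg)
  write_taxonomy(tax, file.path(out_dir, "taxonomy.nwk"),
                 file.path(out_dir, "taxonomy_order.tsv"))
  write_orthoxml(fams, tax, file.path(out_dir, "families.orthoxml"))
  write_ground_truth_tsv(fams, file.path(out_dir, "ground_truth.tsv"))
  bench <- NULL
  if (n_benchmark_pairs > 0L) {
    bench_cfg <- cfg
    bench_cfg$seed <- cfg$seed + 1L
    bench <- make_benchmark(tax, bench_cfg, n_benchmark_pairs)
    write_benchmark_tsv(bench$pairs, file.path(out_dir, "benchmark_pairs.tsv"))
    write_orthoxml(bench$families, tax, file.path(out_dir, "benchmark_families.orthoxml"))
  }
  write_manifest(out_dir, "simulate", config = unclass(cfg),
                 counts = list(n_families = length(fams),
                               rejections = attr(fams, "rejections"),
                               n_benchmark_pairs = n_benchmark_pairs))
  invisible(list(taxonomy = tax, families = fams, benchmark = bench))
}
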