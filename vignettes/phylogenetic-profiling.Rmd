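---
title: "Event-aware phylogenetic profiling with weighted MinHash sketches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-aware phylogenetic profiling with weighted MinHash sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprof)
```

## The problem

Gene families that work together tend to be gained, lost and duplicated
together. Phylogenetic profiling exploits this: each family is summarised by
a vector describing its evolutionary history across a reference species
tree, and families with similar vectors are candidate members of the same
pathway or complex. Two obstacles make this hard at scale. First, naive
presence/absence vectors over extant genomes ignore *where* on the tree
events happened, discarding most of the usable signal. Second, all-vs-all
comparison of hundreds of thousands of families is quadratic, which rules
out exploratory searches.

`phyloprof` addresses both. Families arrive as hierarchical orthologous
groups (HOGs) in OrthoXML; each is reconciled against a named reference
taxonomy into an *event tree* — per taxonomy node: presence, loss,
duplication and copy number. Event trees are flattened into sparse weighted
vectors, sketched as weighted MinHash signatures whose collision rate equals
the weighted Jaccard similarity of the underlying vectors, and indexed in an
LSH Forest that retrieves the top-k most similar families in sub-linear
time. Downstream, all-vs-all Jaccard kernels over small result sets are
clustered with UPGMA to delineate putative modules.

## The model

### Taxonomy as coordinate system

All profiles share one coordinate system: a rooted species tree in which
every node (leaf and internal) carries a unique name and a fixed index.
Indices follow a preorder traversal of the tree as written in the newick
source, so re-loading the same file always reproduces the same indexing —
signatures are only meaningful relative to a taxonomy, and every signature
store carries the full `(index, name, weight)` sidecar plus a checksum.
Pruning to a genome subset keeps every ancestor of a kept leaf and does
*not* collapse single-child nodes: taxonomic levels keep their identity, so
OrthoXML level annotations remain resolvable after pruning.

### Event inference

A family gains at its root taxonomic level. A node is *present* when its
subtree (within the gain clade) retains at least one extant gene. A *loss*
is recorded only at the topmost node of each maximal extinct subtree under
a present parent — one event per loss, matching the view that a loss is a
single evolutionary event. Copy numbers count distinct gene lineages: a
paralog group at level `L` contributes one lineage per copy at `L`, and
nested duplications compound multiplicatively. A *duplication* is flagged
exactly where copy number exceeds the parent's (the parent of the gain
level counts as 1). Paralog groups without an explicit level annotation
inherit the nearest enclosing ortholog group's level.

### Profiles and sketches

The profile space has `3 * n_nodes` columns, coordinate `3 * node_index +
category` with categories presence (0), loss (1) and duplication (2); a
3115-node taxonomy therefore spans 9345 columns. Each event contributes the
node's taxonomy weight to its coordinate; copy numbers beyond the
duplication flag are deliberately not encoded (they remain available on the
event tree for occurrence-profile baselines). Weights default to 1
everywhere; weight 0 acts as a clade filter, and the package guarantees
that zeroing a clade's weights equals deleting those coordinates after the
fact.

Signatures use consistent weighted sampling (Ioffe-style): per hash sample
and coordinate the scheme draws `r, c ~ Gamma(2,1)` and `beta ~ U(0,1)`,
discretises the log-weight as `t = floor(log(w)/r + beta)` and reports the
`(coordinate, t)` pair minimising `log(c) - r(t - beta) - r`. Two profiles
collide on a sample with probability equal to their weighted Jaccard
similarity, so the match fraction of two signatures is an unbiased Jaccard
estimator with standard error `sqrt(J(1-J)/n)`. The scheme is fixed by
`(dim, n, scheme_seed)`; signatures refuse to compare across schemes. The
contract is the collision probability, verified by Monte-Carlo comparison
against the exact `sum(min)/sum(max)` oracle, not any particular internal
representation.

### Retrieval

The `n` samples are split into `l` contiguous slices, one per prefix tree;
two signatures share a prefix of length `j` in a tree with probability
`J^j`. Queries descend from the longest prefix, pooling matches across
trees, until the candidate set reaches `oversample * k` distinct families,
then re-rank every candidate by the full-signature estimate and return the
top `k` (ties broken by insertion order). Prefix identity is tracked by a
rolling hash over sample tokens (prime modulus below 2^26, all arithmetic
exact in doubles); a hash collision can only add a spurious candidate,
which re-ranking discards. Oversampling matters: the first `k` prefix
matches are dominated by near-duplicates, and descending a few levels
further lets moderately similar true neighbours into the candidate pool
before re-ranking.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `n_hashes` | 256 | Samples per signature; estimator SE at most `1/(2*sqrt(256)) ~ 0.031`. |
| `l` (trees) | 8 | Prefix trees of depth `n/l = 32`; the usual recall/cost trade-off. |
| `oversample` | 8 | Candidate budget multiplier before re-ranking. |
| `scheme_seed` | 1 | Fixes the sampling scheme; recorded in every store. |
| taxon weights | 1.0 | Uniform; per-taxon weighting is exposed but unstudied here. |
| UPGMA `cutoff` | free | Merge-height cutoff; a free parameter chosen per analysis. |

Distance for clustering is `1 - estimated Jaccard`. UPGMA merge heights
follow the ultrametric convention — the height of a merge is *half* the
average-linkage distance between the clusters it joins (two items at
distance 2 merge at height 1) — and the flat cut keeps families together
exactly when they merge at height `<= cutoff`. Families are canonically
sorted by id before clustering, which makes the result invariant under
permutation of the kernel and deterministic under ties.

## The simulator

The synthetic-data module makes every stage testable without external
databases. Species trees are random binary trees from uniform coalescent
joins. A family draws a gain node, then on every branch below it is
independently lost (pruning the subtree for all copies) with `loss_rate`
or duplicated (doubling every lineage crossing the branch) with
`dup_rate`; copy numbers are therefore powers of two. Families with no
surviving leaves are rejected and resampled, with the rejection count
reported. Defaults — `loss_rate = 0.15`, `dup_rate = 0.05`, gains uniform
over internal nodes with at least 4 descendant species — describe a
moderately volatile eukaryote-like regime; tiny clades are excluded as
gain points because such families carry almost no profiling signal.

Logged ground truth is canonicalised to *observable* events: losses are
lifted to the topmost fully-extinct node and duplications inside extinct
subtrees are dropped. This is deliberate — the inference stage can only
ever see observable events, so the simulator's log and the inference
convention agree by construction, and the round-trip test (simulate, write
OrthoXML, parse, infer) demands exact recovery on 100% of families.

Co-evolving pairs share the gain node; the partner copies each loss with
probability `coevolution_rho` and adds private losses at rate
`loss_rate * (1 - rho)`, so `rho = 1` with no duplications yields identical
profiles. Benchmarks are balanced by construction: half co-evolving pairs,
half pairs of independent families.

**Benchmark gain placement.** Because partners share their gain node by
definition, a benchmark whose gains vary across the tree is separable from
the gain clade alone — at `rho = 0` the labels would still be almost
perfectly predictable, which defeats the purpose of a co-evolution
benchmark. Benchmark runs therefore place every family's gain at the root:
all profiles span the same clade and the only label signal is the
correlated-loss structure. Under this condition the measured AUC is ~0.5 at
`rho = 0` and rises to 1 at `rho = 1`, and the `rho = 1` check uses
`dup_rate = 0` since duplications are not copied between partners.

What the simulator does *not* emulate: branch lengths and rate
heterogeneity across lineages, horizontal transfer, per-copy (lineage-
specific) losses below a duplication, gene conversion, and annotation
noise in real orthology inference. Passing tests show the pipeline is
correct and well-calibrated under the branch-wise Bernoulli model; they do
not certify performance on real HOGs, where orthology errors and taxon
sampling biases dominate.

## Numerical and design choices

- **Determinism everywhere.** All batch randomness flows from a single
  config seed through a private RNG scope; identical seeds give
  byte-identical OrthoXML, signature stores and cluster assignments.
- **Signature store.** A plain-text directory: `signatures.tsv`
  (families × 2n integer matrix), `meta.json` (n, scheme seed, coordinate
  packing version, taxonomy checksum), the taxonomy newick and its order
  sidecar. Signatures are the source of truth; the forest is rebuilt on
  load rather than serialised.
- **Degenerate inputs are errors, not defaults:** empty profiles cannot be
  signed, the weighted Jaccard of two empty profiles is undefined, Pearson
  on a constant vector is an explicit error (benchmarks drop and count
  such pairs), single-class ROC input is refused, `loss_rate = 1` is
  refused, an odd benchmark size is refused.
- **Ties.** MinHash argmin ties break on the first coordinate (fixed
  order); query ties break by insertion order; UPGMA operates on
  canonically sorted ids.
- **Problem sizes in the test suite** (chosen to exercise each claim at
  meaningful scale): estimator fidelity on 2000 random weighted profile
  pairs; event-recovery closure on 500 families; retrieval recall on 5000
  indexed signatures with 200 queries against a brute-force oracle;
  benchmark separation with 200 pairs per rho on a 100-species tree.

## Limitations

- Copy numbers in simulation are powers of two by construction; real
  families show finer-grained dosage changes the OrthoXML writer does not
  generate (the parser handles them).
- Uniform taxon weights are a placeholder; principled per-level weighting
  is an open question.
- The LSH Forest supports insertion but not deletion; no pipeline stage
  needs deletion.
- Retrieval quality depends on the query's true neighbours being
  moderately similar (estimated Jaccard a few multiples of `1/sqrt(n)`
  above background); families with near-empty profiles retrieve noise.
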