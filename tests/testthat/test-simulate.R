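test_that("simulated taxonomies are binary, named and seed-deterministic", {
  expect_equal(simulate_taxonomy(2, seed = 1)$n_nodes, 3L)
  t100 <- simulate_taxonomy(100, seed = 2)
  expect_equal(t100$n_nodes, 199L)  # 2L - 1 for a binary tree
  expect_identical(taxonomy_to_newick(simulate_taxonomy(40, seed = 9)),
                   taxonomy_to_newick(simulate_taxonomy(40, seed = 9)))
  expect_false(identical(taxonomy_to_newick(simulate_taxonomy(40, seed = 9)),
                         taxonomy_to_newick(simulate_taxonomy(40, seed = 10))))
  expect_error(simulate_taxonomy(1), ">= 2")
})

test_that("event-free families cover their gain clade with one gene per leaf", {
  tax <- simulate_taxonomy(30, seed = 14)
  cfg <- sim_config(n_leaves = 30, loss_rate = 0, dup_rate = 0,
                    gain_node_sampler = "root", seed = 15)
  f <- withr::with_seed(15, simulate_family(tax, cfg))
  expect_true(all(f$present))
  expect_length(f$losses, 0L)
  expect_length(f$duplications, 0L)
  expect_true(all(f$genes == 1))
  expect_equal(sum(f$genes), 30L)
  expect_equal(f$rejections, 0L)
})

test_that("high loss rates trigger rejection-resampling and rate 1 is refused", {
  tax <- simulate_taxonomy(100, seed = 16)
  cfg <- sim_config(n_leaves = 100, loss_rate = 0.95, dup_rate = 0, seed = 17,
                    n_families = 20)
  fams <- simulate_families(tax, cfg)
  expect_gt(attr(fams, "rejections"), 0L)
  cfg1 <- sim_config(n_leaves = 100, loss_rate = 1)
  expect_error(withr::with_seed(1, simulate_family(tax, cfg1)), "loss_rate = 1")
})

test_that("per-branch loss events occur at the configured rate", {
  tax <- simulate_taxonomy(60, seed = 18)
  cfg <- sim_config(n_leaves = 60, loss_rate = 0.1, dup_rate = 0,
                    gain_node_sampler = "root", seed = 19, n_families = 700)
  fams <- simulate_families(tax, cfg)
  # the two branches below the root gain are visited by every family, so the
  # raw loss indicator on them is a clean Bernoulli(loss_rate) sample
  top <- tax$name[tax$children[[1L]]]
  lost <- sum(vapply(fams, function(f) sum(top %in% f$raw_losses), numeric(1)))
  n_branch <- 2 * length(fams)
  rate <- lost / n_branch
  se <- sqrt(0.1 * 0.9 / n_branch)
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("fully correlated partners share exact loss sets and profiles", {
  tax <- simulate_taxonomy(40, seed = 20)
  cfg <- sim_config(n_leaves = 40, loss_rate = 0.2, dup_rate = 0,
                    coevolution_rho = 1, seed = 21)
  for (rep in 1:5) {
    pr <- withr::with_seed(21 + rep, simulate_coevolving_pair(tax, cfg))
    expect_identical(pr$a$losses, pr$b$losses)
    pa <- build_profile(sim_family_event_tree(pr$a, tax), tax)
    pb <- build_profile(sim_family_event_tree(pr$b, tax), tax)
    expect_equal(exact_weighted_jaccard(pa, pb), 1.0)
  }
})

test_that("uncorrelated partners lose branches independently", {
  tax <- simulate_taxonomy(24, seed = 22)
  cfg <- sim_config(n_leaves = 24, loss_rate = 0.3, dup_rate = 0,
                    gain_node_sampler = "root", coevolution_rho = 0, seed = 23)
  top <- tax$name[tax$children[[1L]]]  # branches both partners always visit
  tab <- matrix(0, 2, 2)
  withr::with_seed(23, for (i in 1:300) {
    pr <- simulate_coevolving_pair(tax, cfg)
    for (b in top) {
      ia <- (b %in% pr$a$raw_losses) + 1L
      ib <- (b %in% pr$b$raw_losses) + 1L
      tab[ia, ib] <- tab[ia, ib] + 1
    }
  })
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("correlated-loss pairs are closer than unrelated families", {
  tax <- simulate_taxonomy(40, seed = 24)
  cfg <- sim_config(n_leaves = 40, coevolution_rho = 0.8, seed = 25)
  pas <- vector("list", 100); pbs <- vector("list", 100)
  withr::with_seed(25, for (i in 1:100) {
    pr <- simulate_coevolving_pair(tax, cfg)
    pas[[i]] <- build_profile(sim_family_event_tree(pr$a, tax), tax)
    pbs[[i]] <- build_profile(sim_family_event_tree(pr$b, tax), tax)
  })
  within <- mapply(exact_weighted_jaccard, pas, pbs)
  between <- mapply(exact_weighted_jaccard, pas[-1], pbs[-100])  # unrelated pairs
  expect_lt(stats::wilcox.test(within, between, alternative = "greater")$p.value, 0.01)
})

test_that("the OrthoXML writer is deterministic and round-trips ground truth", {
  tax <- simulate_taxonomy(25, seed = 26)
  cfg <- sim_config(n_leaves = 25, seed = 27, n_families = 150)
  fams <- simulate_families(tax, cfg)
  xml1 <- write_orthoxml(fams, tax)
  xml2 <- write_orthoxml(simulate_families(tax, cfg), tax)
  expect_identical(xml1, xml2)  # byte-identical under the same config + seed
  parsed <- parse_orthoxml(xml1, tax)
  expect_length(parsed, length(fams))
  exact <- 0L
  for (i in seq_along(fams)) {
    ev <- infer_event_tree(parsed[[i]], tax)
    expect_equal(ev$root_level, fams[[i]]$gain)
    gt <- sim_family_event_tree(fams[[i]], tax)
    if (identical(ev$present, gt$present) && identical(ev$lost, gt$lost) &&
        identical(ev$duplicated, gt$duplicated) &&
        identical(ev$copy_number, gt$copy_number)) {
      exact <- exact + 1L
    }
  }
  expect_equal(exact, length(fams))  # 100% recovery
})

test_that("duplications appear as paralog groups at their level", {
  tax <- tax5()
  fam <- structure(list(
    family_id = "dup1", gain = "AB", losses = character(0), duplications = "AB",
    genes = c(A = 2, B = 2), present = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    copy_number = c(0, 2, 2, 2, 0), raw_losses = character(0), rejections = 0L
  ), class = "sim_family")
  xml <- write_orthoxml(list(fam), tax)
  expect_match(xml, "<paralogGroup>")
  ev <- infer_event_tree(parse_orthoxml(xml, tax)[[1L]], tax)
  expect_equal(tax$name[ev$duplicated], "AB")
  expect_equal(ev$copy_number[2:4], c(2L, 2L, 2L))
})

test_that("families without genes cannot be serialised", {
  tax <- tax5()
  fam <- structure(list(family_id = "x", gain = "AB", losses = character(0),
                        duplications = character(0), genes = numeric(0),
                        present = rep(FALSE, 5), copy_number = rep(0, 5),
                        raw_losses = character(0), rejections = 0L),
                   class = "sim_family")
  expect_error(write_orthoxml(list(fam), tax), "no genes")
})

test_that("benchmarks are balanced and labelled by construction", {
  tax <- simulate_taxonomy(30, seed = 28)
  cfg <- sim_config(n_leaves = 30, seed = 29)
  expect_error(make_benchmark(tax, cfg, 9), "even")
  bench <- make_benchmark(tax, cfg, 10)
  expect_equal(nrow(bench$pairs), 10L)
  expect_equal(sum(bench$pairs$label == "interacting"), 5L)
  expect_equal(sum(bench$pairs$label == "non-interacting"), 5L)
  expect_length(bench$families, 20L)
  expect_true(all(c(bench$pairs$id_a, bench$pairs$id_b) %in% names(bench$families)))
})
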