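test_that("species-tree simulation is ultrametric and seed-deterministic", {
  tr <- simulate_species_tree(44, seed = 3)
  expect_identical(length(tr$tip.label), 44L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_identical(write_newick(simulate_species_tree(44, seed = 3)),
                   write_newick(tr))
  tiny <- simulate_species_tree(2, seed = 1)
  expect_identical(length(tiny$tip.label), 2L)
  expect_error(simulate_species_tree(1), ">= 2")
})

test_that("zero rates give vertical inheritance everywhere", {
  sp <- simulate_species_tree(12, seed = 5)
  h <- simulate_operon_history(sp, 0, 0, seed = 1)
  expect_identical(nrow(h$events), 0L)
  expect_true(all(h$presence))
  expect_identical(rf_dist(h$operon_tree, sp), 0L)
  expect_true(ape::is.ultrametric(h$operon_tree, tol = 1e-6))
  g <- simulate_gene_trees(h, 0, 4, seed = 2)
  for (t in g$trees) expect_identical(rf_dist(t, h$operon_tree), 0L)
})

test_that("loss-only histories restrict the species tree to carriers", {
  set.seed(7)
  for (i in 1:10) {
    sp <- simulate_species_tree(12, seed = 100 + i)
    h <- simulate_operon_history(sp, 0, 0.25, seed = 200 + i)
    expect_identical(unname(h$n_losses), sum(h$events$type == "loss"))
    expect_identical(sort(names(h$presence)[h$presence]),
                     sort(if (is.null(h$operon_tree)) character(0) else
                       h$operon_tree$tip.label))
    if (sum(h$presence) >= 3L) {
      induced <- prune_to_taxa(sp, names(h$presence)[h$presence])
      expect_identical(rf_dist(h$operon_tree, induced), 0L)
    }
  }
})

test_that("whole histories are byte-deterministic under the seed", {
  sp <- simulate_species_tree(20, seed = 11)
  a <- simulate_operon_history(sp, 0.3, 0.15, seed = 13)
  b <- simulate_operon_history(sp, 0.3, 0.15, seed = 13)
  expect_identical(a$events, b$events)
  expect_identical(write_newick(a$operon_tree), write_newick(b$operon_tree))
  ga <- simulate_gene_trees(a, 0.05, 5, seed = 17)
  gb <- simulate_gene_trees(b, 0.05, 5, seed = 17)
  expect_identical(lapply(ga$trees, write_newick),
                   lapply(gb$trees, write_newick))
  bun1 <- simulate_study_bundle(n_species = 12, n_genes = 4, seed = 19)
  bun2 <- simulate_study_bundle(n_species = 12, n_genes = 4, seed = 19)
  expect_identical(write_newick(bun1$operon_tree),
                   write_newick(bun2$operon_tree))
})

test_that("realised transfer counts are consistent with the rates", {
  # per replicate, transfers | carrier exposure ~ Poisson(rate * exposure);
  # the mean of (count - rate * exposure) should be 0 within 3 SE
  sp <- simulate_species_tree(10, seed = 23)
  rate <- 0.3
  n_rep <- 1000L
  d <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    h <- simulate_operon_history(sp, rate, 0.1, seed = 3000 + i)
    exposure <- sum(h$carrier_intervals$to - h$carrier_intervals$from)
    d[i] <- h$n_transfers - rate * exposure
  }
  se <- stats::sd(d) / sqrt(n_rep)
  expect_lt(abs(mean(d)), 3 * se + 1e-9)
})

test_that("per-gene transfers are Poisson-consistent with the gene rate", {
  sp <- simulate_species_tree(10, seed = 29)
  h <- simulate_operon_history(sp, 0, 0, seed = 1)
  exposure <- sum(h$carrier_intervals$to - h$carrier_intervals$from)
  rate <- 0.1
  g <- simulate_gene_trees(h, rate, 400, seed = 31)
  counts <- vapply(g$events, nrow, 1L)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - rate * exposure), 3 * se + 1e-9)
})

test_that("a planted gene transfer shows up in that gene only", {
  sp <- simulate_species_tree(10, seed = 37)
  h <- simulate_operon_history(sp, 0, 0, seed = 1)
  ph <- simulate_planted_hots(sp, 1L, seed = 41)
  planted <- data.frame(gene = 3L, time = ph$events$time[1L],
                        donor = ph$events$donor[1L],
                        recipient = ph$events$recipient[1L])
  g <- simulate_gene_trees(h, 0, 5, seed = 2, planted = planted)
  for (i in seq_len(5L)) {
    d <- rf_dist(g$trees[[i]], h$operon_tree)
    if (i == 3L) expect_gt(d, 0L) else expect_identical(d, 0L)
  }
  # ground truth: the gene differs from the operon genealogy by one SPR,
  # i.e. reconciles against it with exactly one transfer
  rec <- dtl_reconcile(g$trees[[3L]], h$operon_tree)
  expect_identical(unname(rec$summary[["transfers"]]), 1L)
  bad <- data.frame(gene = 1L, time = -5, donor = 1L, recipient = 2L)
  expect_error(simulate_gene_trees(h, 0, 2, seed = 2, planted = bad),
               "carrier")
})

test_that("planted operon transfers are recovered by reconciliation", {
  set.seed(43)
  for (i in 1:5) {
    sp <- simulate_species_tree(30, seed = 4000 + i)
    h <- simulate_planted_hots(sp, 3L, seed = 4100 + i)
    expect_identical(unname(h$n_transfers), 3L)
    expect_true(all(h$presence))
    rec <- dtl_reconcile(h$operon_tree, sp)
    expect_identical(unname(rec$summary[["transfers"]]), 3L)
  }
  # logged surviving transfers always bound the parsimony estimate
  for (i in 1:5) {
    sp <- simulate_species_tree(15, seed = 4200 + i)
    h <- simulate_operon_history(sp, 0.3, 0.1, seed = 4300 + i)
    if (sum(h$presence) < 4L) next
    rec <- dtl_reconcile(h$operon_tree, sp)
    expect_lte(unname(rec$summary[["transfers"]]), h$n_transfers)
  }
})

test_that("support assignment hits internal non-root edges only", {
  sp <- simulate_species_tree(10, seed = 47)
  st <- assign_supports(sp)
  expect_identical(st$node.label[1L], "")             # root: none
  expect_true(all(st$node.label[-1L] == "100"))
  lo <- assign_supports(sp, n_low = 3, low_support = 40, seed = 53)
  expect_identical(sum(lo$node.label == "40"), 3L)
  lo2 <- assign_supports(sp, n_low = 3, low_support = 40, seed = 53)
  expect_identical(lo$node.label, lo2$node.label)
})

test_that("NNI perturbation swaps exactly one bipartition per interchange", {
  sp <- assign_supports(simulate_species_tree(12, seed = 59))
  expect_identical(write_newick(perturb_topology(sp, 0L)),
                   write_newick(sp))
  p1 <- perturb_topology(sp, 1L, low_support = 40, seed = 61)
  expect_identical(rf_dist(p1, sp), 2L)
  bs <- bipartition_set(p1)
  new_split <- setdiff(bs$split, bipartition_set(sp)$split)
  expect_identical(bs$support[bs$split == new_split], 40)
  expect_error(perturb_topology(sp, 1000L), "exceeds")
})
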