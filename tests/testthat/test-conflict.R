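test_that("identical trees yield no conflicts", {
  tr <- nwk("((((A,B)100,C)100,D)100,E);")
  expect_identical(nrow(find_supported_conflicts(tr, tr)), 0L)
})

test_that("supported incompatible splits are detected; threshold is strict", {
  ref <- nwk("((((A,C)90,B)90,D)90,E);")
  assoc98 <- nwk("((((A,B)98,C)98,D)98,E);")
  rec <- find_supported_conflicts(assoc98, ref)
  expect_identical(rec$split[1L], "A,B")
  expect_gte(rec$n_ref_incompatible[1L], 1L)
  expect_identical(rec$max_ref_support[rec$split == "A,B"], 90)

  # boundary: support exactly at the threshold is not a conflict
  assoc70 <- nwk("((((A,B)70,C)98,D)98,E);")
  expect_false("A,B" %in% find_supported_conflicts(assoc70, ref)$split)

  # unsupported edges never trigger records
  assoc_na <- nwk("((((A,B),C)98,D)98,E);")
  expect_false("A,B" %in% find_supported_conflicts(assoc_na, ref)$split)
})

test_that("detection is monotone in the support threshold", {
  set.seed(53)
  for (i in 1:10) {
    ref <- random_rooted_tree(paste0("t", 1:8))
    assoc <- with_random_supports(perturb_topology(
      assign_supports(random_rooted_tree(paste0("t", 1:8))), 0L), 900 + i)
    n_prev <- Inf
    for (th in c(0, 40, 70, 90)) {
      n <- nrow(find_supported_conflicts(assoc, ref, theta_assoc = th))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("triage order is fixable, then reference-uncertain, then authentic", {
  # a perturbation behind a weak (40) edge: detected at a low scan
  # threshold, repaired by fixing at 70, hence fixable
  ref <- assign_supports(nwk("(((A,B),C),((D,E),F));"))
  weak <- perturb_topology(ref, 1L, low_support = 40, seed = 61)
  rec <- find_supported_conflicts(weak, ref, theta_assoc = 30)
  expect_gte(nrow(rec), 1L)
  fixed <- fix_tree(weak, ref, support_threshold = 70)$tree
  cls <- classify_conflicts(rec, ref, fixed, theta_ref = 70)
  expect_true(all(cls$class == "fixable"))

  # a strongly supported conflict against a weak reference edge survives
  # fixing and lands on reference uncertainty (boundary <= 70)
  ref2 <- nwk("((((A,C)70,B)100,D)100,E);")
  assoc2 <- nwk("((((A,B)95,C)100,D)100,E);")
  rec2 <- find_supported_conflicts(assoc2, ref2)
  fixed2 <- fix_tree(assoc2, ref2, support_threshold = 70)$tree
  cls2 <- classify_conflicts(rec2, ref2, fixed2)
  expect_identical(unique(cls2$class), "reference_uncertain")

  # against a maximally supported reference edge: authentic
  ref3 <- nwk("((((A,C)100,B)100,D)100,E);")
  rec3 <- find_supported_conflicts(assoc2, ref3)
  fixed3 <- fix_tree(assoc2, ref3, support_threshold = 70)$tree
  cls3 <- classify_conflicts(rec3, ref3, fixed3)
  expect_identical(unique(cls3$class), "authentic_hgt")

  # classes partition the records
  expect_identical(sum(table(cls3$class)), nrow(rec3))
  expect_error(classify_conflicts(rec3, ref3, nwk("((A,B),(C,Z));")),
               "taxon set")
})

test_that("gene-set scanning pinpoints the transferred gene", {
  sp <- simulate_species_tree(16, seed = 67)
  h <- simulate_operon_history(sp, 0, 0, seed = 1)
  genes <- simulate_gene_trees(h, 0, 10, seed = 2)

  # noise-free: no gene conflicts with the operon tree
  ref <- assign_supports(h$operon_tree)
  gts <- lapply(genes$trees, assign_supports)
  res0 <- scan_gene_set(gts, ref)
  expect_identical(unname(res0$totals[["conflicts"]]), 0L)
  expect_identical(res0$flagged_genes, character(0))

  # plant one full-support transfer in gene 5 only
  ph <- simulate_planted_hots(sp, 1L, seed = 71)
  planted <- data.frame(gene = 5L, time = ph$events$time[1L],
                        donor = ph$events$donor[1L],
                        recipient = ph$events$recipient[1L])
  genes_p <- simulate_gene_trees(h, 0, 10, seed = 2, planted = planted)
  gts_p <- lapply(genes_p$trees, assign_supports)
  res1 <- scan_gene_set(gts_p, ref)
  expect_identical(res1$flagged_genes, "g05")
  expect_gte(res1$per_gene$authentic_hgt[res1$per_gene$gene == "g05"], 1L)
  expect_identical(sum(res1$per_gene$authentic_hgt[
    res1$per_gene$gene != "g05"]), 0L)
  # class counts sum to the record count
  expect_identical(unname(res1$totals[["conflicts"]]),
                   unname(sum(res1$totals[c("fixable",
                                            "reference_uncertain",
                                            "authentic_hgt")])))

  # the same event with supports degraded below the threshold vanishes
  gts_weak <- lapply(genes_p$trees, assign_supports, support = 65)
  res2 <- scan_gene_set(gts_weak, ref)
  expect_identical(unname(res2$totals[["conflicts"]]), 0L)

  expect_error(scan_gene_set(list(), ref), "nonempty")
})

test_that("disjoint taxon sets are rejected, partial overlap is pruned", {
  a <- nwk("((A,B)90,(C,D)90);")
  b <- nwk("((E,F),(G,H));")
  expect_error(find_supported_conflicts(a, b), "fewer than 2")
  c1 <- nwk("(((A,B)90,C)90,(D,E)90);")
  c2 <- nwk("(((A,B),C),D);")
  expect_message(find_supported_conflicts(c1, c2), "pruned")
})
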