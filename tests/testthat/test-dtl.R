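test_that("identical trees reconcile at cost zero with speciations only", {
  sp <- nwk("((A,B),(C,D));")
  rec <- dtl_reconcile(sp, sp)
  expect_identical(rec$cost, 0)
  expect_identical(rec$n_optimal, 1)
  expect_identical(unname(rec$summary),
                   c(3L, 0L, 0L, 0L))
  expect_identical(nrow(rec$events[rec$events$kind != "speciation", ]), 0L)
})

test_that("small worked examples match the brute-force oracle", {
  # one displaced taxon: a single transfer, cost 3
  sp <- nwk("((A,B),C);")
  gn <- nwk("((A,C),B);")
  o <- oracle_dtl(gn, sp)
  expect_identical(o$cost, 3)
  rec <- dtl_reconcile(gn, sp)
  expect_identical(rec$cost, 3)
  expect_identical(rec$n_optimal, o$n_optimal)
  expect_identical(unname(rec$summary[["transfers"]]), 1L)

  # absent taxon: one loss on the D edge
  sp4 <- nwk("((A,B),(C,D));")
  g3 <- nwk("((A,B),C);")
  o <- oracle_dtl(g3, sp4)
  expect_identical(o$cost, 1)
  rec <- dtl_reconcile(g3, sp4)
  expect_identical(rec$cost, 1)
  expect_identical(unname(rec$summary[["losses"]]), 1L)
  expect_identical(rec$events$species_node[rec$events$kind == "loss"], "D")

  # in-paralogs: one duplication on the A edge
  gd <- nwk("((A1,A2),B);")
  spd <- nwk("((A,B),C);")
  lm <- c(A1 = "A", A2 = "A", B = "B")
  o <- oracle_dtl(gd, spd, leaf_map = lm)
  expect_identical(o$cost, 2)
  rec <- dtl_reconcile(gd, spd, leaf_map = lm)
  expect_identical(rec$cost, 2)
  expect_identical(unname(rec$summary[["duplications"]]), 1L)
  expect_identical(rec$events$species_node[rec$events$kind == "duplication"],
                   "A")
})

test_that("DP cost and co-optimal count equal the oracle on random pairs", {
  set.seed(23)
  for (i in 1:40) {
    ns <- sample(4:6, 1L)
    ngl <- sample(3:min(ns, 5L), 1L)
    stree <- random_rooted_tree(paste0("s", seq_len(ns)))
    gtree <- random_rooted_tree(paste0("g", seq_len(ngl)))
    lm <- stats::setNames(
      sample(paste0("s", seq_len(ns)), ngl, replace = runif(1) < 0.3),
      paste0("g", seq_len(ngl))
    )
    o <- oracle_dtl(gtree, stree, leaf_map = lm)
    d <- dtl_reconcile(gtree, stree, leaf_map = lm)
    expect_identical(d$cost, o$cost)
    expect_identical(d$n_optimal, o$n_optimal)
  }
})

test_that("scenario enumeration is exhaustive and consistent", {
  sp <- nwk("((A,B),C);")
  gn <- nwk("((A,C),B);")
  scs <- enumerate_scenarios(gn, sp, limit = 1000L)
  expect_identical(length(scs), as.integer(attr(scs, "n_optimal")))
  one <- enumerate_scenarios(gn, sp, limit = 1L)
  expect_identical(length(one), 1L)
  rec <- dtl_reconcile(gn, sp)
  expect_identical(one[[1L]]$events, rec$events)
  expect_identical(one[[1L]]$mapping, rec$mapping)
  expect_error(enumerate_scenarios(gn, sp, limit = 0L), ">= 1")

  # identical trees: exactly one scenario
  expect_identical(length(enumerate_scenarios(sp, sp, limit = 10L)), 1L)

  set.seed(29)
  for (i in 1:15) {
    stree <- random_rooted_tree(paste0("s", 1:5))
    gtree <- random_rooted_tree(paste0("s", 1:4))
    d <- dtl_reconcile(gtree, stree)
    scs <- enumerate_scenarios(gtree, stree, limit = 100000L)
    expect_identical(length(scs), as.integer(d$n_optimal))
    # scenarios are pairwise distinct (mapping + events)
    keys <- vapply(scs, function(s) {
      paste(c(paste(names(s$mapping), s$mapping, collapse = ";"),
              paste(apply(s$events, 1L, paste, collapse = "|"),
                    collapse = ";")), collapse = "#")
    }, character(1L))
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("gene trees isomorphic to the species tree cost zero uniquely", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:12, 1L)
    sp <- random_rooted_tree(paste0("s", seq_len(n)))
    rec <- dtl_reconcile(sp, sp)
    expect_identical(rec$cost, 0)
    expect_identical(rec$n_optimal, 1)
  }
})

test_that("one SPR costs at most transfer + loss, with exactly one transfer", {
  set.seed(37)
  for (i in 1:12) {
    sp <- simulate_species_tree(sample(5:7, 1L), seed = 700 + i)
    h <- simulate_planted_hots(sp, 1L, seed = 800 + i)
    rec <- dtl_reconcile(h$operon_tree, sp)
    o <- oracle_dtl(h$operon_tree, sp)
    expect_identical(rec$cost, o$cost)
    expect_lte(rec$cost, 3 + 1)
    expect_identical(unname(rec$summary[["transfers"]]), 1L)
  }
})

test_that("optimal cost is monotone in every single event cost", {
  set.seed(41)
  for (i in 1:10) {
    sp <- random_rooted_tree(paste0("s", 1:6))
    gn <- random_rooted_tree(paste0("s", 1:5))
    base <- dtl_reconcile(gn, sp)$cost
    for (bump in list(dtl_costs(dup = 3), dtl_costs(transfer = 4),
                      dtl_costs(loss = 2))) {
      expect_gte(dtl_reconcile(gn, sp, costs = bump)$cost, base)
    }
  }
})

test_that("reconciliation rejects malformed input", {
  sp <- nwk("((A,B),C);")
  expect_error(dtl_reconcile(nwk("(A,B,C);"), sp), "binary")
  expect_error(dtl_reconcile(sp, nwk("(A,B,C);")), "binary")
  expect_error(dtl_reconcile(nwk("((A,Z),B);"), sp), "absent")
  expect_error(dtl_costs(dup = -1), "non-negative")
})

test_that("Dollo loss count equals the maximal all-absent clades", {
  sp <- nwk("((A,B),(C,D));")
  all_present <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE)
  expect_identical(dollo_loss_count(sp, all_present)$n_losses, 0L)

  one <- dollo_loss_count(sp, c(A = TRUE, B = TRUE, C = FALSE, D = FALSE))
  expect_identical(one$n_losses, 1L)
  expect_identical(one$loss_edges$tips, "C,D")

  two <- dollo_loss_count(sp, c(A = TRUE, B = FALSE, C = FALSE, D = TRUE))
  expect_identical(two$n_losses, 2L)
  expect_identical(two$loss_edges$tips, c("B", "C"))

  expect_error(dollo_loss_count(sp, c(A = TRUE, B = TRUE, C = TRUE,
                                      Z = FALSE)),
               "unknown leaf")
  expect_error(dollo_loss_count(sp, c(A = TRUE, B = TRUE, C = TRUE)),
               "missing")
})

test_that("Dollo count matches the exhaustive-assignment oracle", {
  set.seed(43)
  for (i in 1:30) {
    tr <- random_rooted_tree(paste0("t", 1:10))
    pres <- stats::setNames(sample(c(TRUE, FALSE), 10L, replace = TRUE),
                            paste0("t", 1:10))
    got <- dollo_loss_count(tr, pres)$n_losses
    expect_identical(got, as.integer(oracle_dollo(tr, pres)))
  }
})
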