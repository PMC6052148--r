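test_that("newick parsing reads supports, rescales proportions, and validates", {
  tr <- nwk("((A:1,B:1)95:2,(C:1,D:1)100:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_setequal(setdiff(tr$node.label, ""), c("95", "100"))

  expect_message(tr2 <- read_newick(text = "((A,B)0.95,(C,D)1.0);"),
                 "rescaled")
  expect_setequal(setdiff(tr2$node.label, ""), c("95", "100"))

  expect_error(read_newick(text = "((A,B),(A,C));"), "duplicate leaf.*A")
  expect_error(read_newick(text = "((A,B),(C,D);"),
               "unbalanced parentheses")
  expect_error(read_newick(text = "((A,B)150,(C,D));"), "outside \\[0,100\\]")
  expect_error(read_newick(), "exactly one")
})

test_that("serialize/parse round-trips trees exactly", {
  # double serialisation is a fixed point: serialize(parse(serialize(t)))
  # equals serialize(t), including supports and lengths
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:64, 1L)
    tr <- random_rooted_tree(paste0("t", seq_len(n)))
    if (i %% 3 == 0L) tr <- with_random_supports(tr, seed = i)
    if (i %% 4 == 0L) tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
    s1 <- write_newick(tr)
    re <- suppressMessages(read_newick(text = s1))
    expect_identical(write_newick(re), s1)
    expect_setequal(re$tip.label, tr$tip.label)
  }
})

test_that("bipartition sets have n-3 entries for binary trees", {
  cat5 <- nwk("((((A,B),C),D),E);")
  bs <- bipartition_set(cat5)
  expect_identical(bs$split, c("A,B", "A,B,C"))
  expect_identical(nrow(bipartition_set(nwk("((A,B),(C,D));"))), 1L)
  expect_identical(nrow(bipartition_set(nwk("(A,B,C);"))), 0L)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:20, 1L)
    tr <- random_rooted_tree(paste0("t", seq_len(n)))
    expect_identical(nrow(bipartition_set(tr)), n - 3L)
  }
})

test_that("compatibility matches the four-intersection definition", {
  taxa4 <- LETTERS[1:4]
  expect_false(are_compatible(bipartition(c("A", "B"), taxa4),
                              bipartition(c("A", "C"), taxa4)))
  taxa5 <- LETTERS[1:5]
  expect_true(are_compatible(bipartition(c("A", "B"), taxa5),
                             bipartition(c("A", "B", "C"), taxa5)))
  b <- bipartition(c("A", "B"), taxa4)
  expect_true(are_compatible(b, b))
  expect_error(are_compatible(b, bipartition("A", LETTERS[1:3])),
               "different taxon sets")
  set.seed(11)
  taxa <- paste0("t", 1:8)
  for (i in 1:200) {
    s1 <- sample(taxa, sample(1:7, 1L))
    s2 <- sample(taxa, sample(1:7, 1L))
    b1 <- bipartition(s1, taxa)
    b2 <- bipartition(s2, taxa)
    expect_identical(are_compatible(b1, b2), oracle_compatible(b1, b2))
  }
})

test_that("outgroup rooting places the outgroup as sister and keeps splits", {
  tr <- nwk("((((A,B)80,C)60,D)90,E);")
  r <- root_with_outgroup(tr, "E")
  it <- hotrecon:::as_itree(r)
  kids <- it$children[[it$root]]
  kid_tips <- lapply(kids, function(v) hotrecon:::itree_clades(it)[[v]])
  expect_true(any(vapply(kid_tips, identical, TRUE, y = "E")))
  expect_identical(bipartition_set(r)$split, bipartition_set(tr)$split)

  r2 <- root_with_outgroup(tr, c("A", "B"))
  expect_identical(bipartition_set(r2)$split, bipartition_set(tr)$split)
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D", "E")),
               "proper subset")
  expect_error(root_with_outgroup(tr, c("A", "D")), "not a clade.*A, D")
})

test_that("collapsing contracts strictly sub-threshold edges only", {
  tr <- nwk("((((A,B)100,C)40,D)100,E);")
  cl <- collapse_low_support(tr, 70)
  expect_identical(bipartition_set(cl)$split, "A,B")
  expect_setequal(cl$tip.label, tr$tip.label)

  # boundary: support exactly at the threshold is retained
  tr70 <- nwk("((((A,B)100,C)70,D)100,E);")
  expect_identical(bipartition_set(collapse_low_support(tr70, 70))$split,
                   c("A,B", "A,B,C"))
  # unchanged when everything is strong; missing supports never collapse
  expect_identical(
    bipartition_set(collapse_low_support(nwk("(((A,B),C),D);"), 70))$split,
    "A,B"
  )
  expect_error(collapse_low_support(tr, 101), "\\[0, 100\\]")

  set.seed(13)
  for (i in 1:20) {
    tr <- with_random_supports(random_rooted_tree(paste0("t", 1:10)),
                               seed = 500 + i)
    cc <- collapse_low_support(tr, 70)
    expect_setequal(cc$tip.label, tr$tip.label)
    bs <- bipartition_set(tr)
    strong <- bs$split[!is.na(bs$support) & bs$support >= 70]
    expect_true(all(strong %in% bipartition_set(cc)$split))
  }
})

test_that("pruning keeps structure and errors on unknown taxa", {
  tr <- nwk("((((A,B)80,C)60,D)90,E);")
  p <- prune_to_taxa(tr, c("A", "B", "D"))
  expect_setequal(p$tip.label, c("A", "B", "D"))
  expect_identical(bipartition_set(p)$split, character(0))
  expect_error(prune_to_taxa(tr, c("A", "Z")), "absent.*Z")
})
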