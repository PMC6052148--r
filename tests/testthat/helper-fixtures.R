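# shared shortcuts for building small fixtures in code

nwk <- function(s) suppressMessages(read_newick(text = s))

# random supports drawn from a fixed palette, attached to a binary tree
with_random_supports <- function(tree, seed) {
  set.seed(seed)
  nd <- hotrecon:::as_tnode(tree)
  rec <- function(n, is_root) {
    if (hotrecon:::t_is_leaf(n)) return(n)
    n$children <- lapply(n$children, rec, is_root = FALSE)
    if (!is_root) n$support <- sample(c(20, 40, 60, 70, 85, 100), 1L)
    n
  }
  hotrecon:::tnode_to_phylo(rec(nd, TRUE))
}
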