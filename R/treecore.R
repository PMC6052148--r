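#' Read a rooted tree with edge supports from newick
#'
#' Parses a newick string or file into an [ape::phylo] object and validates
#' it for use in the reconciliation pipeline.  Numeric internal-node labels
#' are interpreted as bootstrap supports on the subtending edge (the common
#' RAxML convention).  When every numeric support lies in \[0, 1\] the whole
#' tree is taken to use bootstrap proportions and supports are rescaled to
#' percentages (a message records the rescaling).  Non-numeric internal
#' labels are preserved as names.  Square-bracket comments are discarded and
#' quoted labels are honoured (both via the ape reader).
#'
#' @param file path to a newick file (exactly one of `file`/`text`).
#' @param text a newick string.
#' @return an object of class `phylo`; supports remain in `node.label`.
#' @details Errors are raised for unbalanced parentheses (with the offset of
#'   the first unmatched character), duplicate leaf labels (naming the
#'   label), and supports outside \[0, 100\] after rescaling.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1)95:2,(C:1,D:1)100:2);")
#' tr$node.label
#' @seealso [write_newick()], [bipartition_set()]
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`")
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  .check_parens(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("newick parse error: no tree found in input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  .normalise_supports(phy)
}

.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced parentheses: unmatched ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses: ", depth, " '(' left open at end of input")
  }
  invisible(TRUE)
}

# rescale proportion supports to percent and validate the range
.normalise_supports <- function(phy) {
  nl <- phy$node.label
  if (is.null(nl)) return(phy)
  sup <- .parse_supports(nl)
  num <- which(!is.na(sup))
  if (length(num) > 0L) {
    if (all(sup[num] >= 0 & sup[num] <= 1)) {
      sup[num] <- sup[num] * 100
      phy$node.label[num] <- .fmt_num(sup[num])
      message("supports in [0,1] rescaled to percentages")
    }
    bad <- num[sup[num] < 0 | sup[num] > 100]
    if (length(bad) > 0L) {
      stop("support value(s) outside [0,100]: ",
           paste(unique(nl[bad]), collapse = ", "))
    }
  }
  phy
}

#' Serialise a tree to newick
#'
#' Writes supports back as internal-node labels so that
#' `read_newick(text = write_newick(tr))` round-trips the tree (up to child
#' order and numeric formatting).
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written there.
#' @return the newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- tnode_to_newick(as_tnode(tree))
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Construct a bipartition of a taxon set
#'
#' A bipartition splits the full taxon set into two disjoint nonempty sides;
#' it is the combinatorial object induced by removing one tree edge.  The
#' canonical orientation stores first the side containing the
#' lexicographically smallest taxon, so equality is well defined.
#'
#' @param side character vector, one side of the split.
#' @param taxa character vector, the full taxon set.
#' @return an object of class `hot_bipartition` with elements `side1`,
#'   `side2` (sorted; `side1` holds the smallest taxon).
#' @examples
#' bipartition(c("C", "D"), LETTERS[1:4])
#' @export
bipartition <- function(side, taxa) {
  side <- unique(as.character(side))
  taxa <- unique(as.character(taxa))
  if (!all(side %in% taxa)) {
    stop("side contains taxa absent from the taxon set: ",
         paste(setdiff(side, taxa), collapse = ", "))
  }
  other <- setdiff(taxa, side)
  if (length(side) == 0L || length(other) == 0L) {
    stop("both sides of a bipartition must be nonempty")
  }
  s1 <- sort(side)
  s2 <- sort(other)
  if (s2[1L] < s1[1L]) {
    tmp <- s1
    s1 <- s2
    s2 <- tmp
  }
  structure(list(side1 = s1, side2 = s2), class = "hot_bipartition")
}

#' @export
print.hot_bipartition <- function(x, ...) {
  cat(paste(x$side1, collapse = ","), "|", paste(x$side2, collapse = ","),
      "\n")
  invisible(x)
}

#' @export
format.hot_bipartition <- function(x, ...) {
  paste0(paste(x$side1, collapse = ","), "|", paste(x$side2, collapse = ","))
}

# canonical single-string key for set membership tests: the smaller-taxon
# side, comma-joined (the full taxon set disambiguates the rest)
bip_key <- function(b) paste(b$side1, collapse = ",")

#' Non-trivial bipartitions of a tree, with their supports
#'
#' One entry per internal non-root edge whose split is non-trivial (neither
#' side a singleton).  The two root-child edges of a rooted tree induce the
#' same unrooted split; it is reported once, carrying the larger of the two
#' supports when both are annotated.
#'
#' @param tree a `phylo` object.
#' @return a data frame with columns `split` (canonical key: sorted taxa of
#'   the side containing the alphabetically smallest taxon, comma-joined)
#'   and `support` (percent; `NA` marks an unsupported edge), sorted by
#'   `split`, with the full taxon set in `attr(, "taxa")`.
#' @examples
#' bipartition_set(read_newick(text = "((A,B)95,(C,D)87);"))
#' @export
bipartition_set <- function(tree) {
  it <- as_itree(tree)
  taxa <- sort(it$label[it$is_tip])
  n <- length(taxa)
  cl <- itree_clades(it)
  keys <- character(0)
  sups <- numeric(0)
  for (v in seq_len(it$n)) {
    if (v == it$root || it$is_tip[v]) next
    side <- cl[[v]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    b <- bipartition(side, taxa)
    keys <- c(keys, bip_key(b))
    sups <- c(sups, it$support[v])
  }
  if (length(keys) > 0L && anyDuplicated(keys)) {
    agg <- tapply(sups, keys, function(s) {
      if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    })
    keys <- names(agg)
    sups <- as.numeric(agg)
  }
  o <- order(keys)
  out <- data.frame(split = keys[o], support = sups[o],
                    stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  out
}

# rebuild a hot_bipartition from a canonical key and the taxon set
key_to_bip <- function(key, taxa) {
  bipartition(strsplit(key, ",", fixed = TRUE)[[1L]], taxa)
}

#' Test whether two bipartitions are compatible
#'
#' Two bipartitions of the same taxon set are compatible iff at least one of
#' the four pairwise side intersections is empty — exactly when both can be
#' realised as edges of a single tree.
#'
#' @param b1,b2 `hot_bipartition` objects on the same taxon set.
#' @return `TRUE` or `FALSE`.
#' @export
are_compatible <- function(b1, b2) {
  stopifnot(inherits(b1, "hot_bipartition"), inherits(b2, "hot_bipartition"))
  t1 <- c(b1$side1, b1$side2)
  t2 <- c(b2$side1, b2$side2)
  if (!setequal(t1, t2)) {
    stop("bipartitions are on different taxon sets")
  }
  length(intersect(b1$side1, b2$side1)) == 0L ||
    length(intersect(b1$side1, b2$side2)) == 0L ||
    length(intersect(b1$side2, b2$side1)) == 0L ||
    length(intersect(b1$side2, b2$side2)) == 0L
}

#' Root a tree on the edge separating an outgroup from the ingroup
#'
#' The outgroup must form a clade in the unrooted sense; the returned tree is
#' rooted such that the outgroup is sister to everything else.  The unrooted
#' bipartition set (and its supports) is unchanged.
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup taxa.
#' @return a rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  phy <- as_phylo(tree)
  outgroup <- unique(as.character(outgroup))
  tips <- phy$tip.label
  missing <- setdiff(outgroup, tips)
  if (length(missing) > 0L) {
    stop("outgroup taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(outgroup) >= length(tips)) {
    stop("outgroup must be a proper subset of the taxa")
  }
  it <- as_itree(phy)
  cl <- itree_clades(it)
  ok <- FALSE
  og <- sort(outgroup)
  for (v in seq_len(it$n)) {
    if (v == it$root) next
    side <- cl[[v]]
    if (identical(side, og) || identical(sort(setdiff(tips, side)), og)) {
      ok <- TRUE
      break
    }
  }
  if (!ok) {
    stop("outgroup is not a clade in the unrooted tree: ",
         paste(og, collapse = ", "))
  }
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!is.null(rooted$node.label)) rooted$node.label[1L] <- ""
  rooted
}

#' Collapse weakly supported edges into polytomies
#'
#' Contracts every internal edge whose support is strictly below `threshold`.
#' Edges with support exactly at the threshold, and edges carrying no support
#' value at all, are retained: missing support is treated as
#' not-contradicted, a deliberately conservative choice for the fixing stage.
#' The length of a contracted edge is added to its promoted children so tip
#' depths are preserved.
#'
#' @param tree a `phylo` object.
#' @param threshold percent in \[0, 100\].
#' @return a `phylo` object, possibly multifurcating; leaf set unchanged.
#' @export
collapse_low_support <- function(tree, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 100) {
    stop("threshold must be a single value in [0, 100]")
  }
  nd <- as_tnode(tree)
  rec <- function(n) {
    if (t_is_leaf(n)) return(n)
    out <- list()
    for (ch in lapply(n$children, rec)) {
      if (!t_is_leaf(ch) && !is.na(ch$support) && ch$support < threshold) {
        for (g in ch$children) {
          if (!is.na(ch$length)) {
            g$length <- (if (is.na(g$length)) 0 else g$length) + ch$length
          }
          out[[length(out) + 1L]] <- g
        }
      } else {
        out[[length(out) + 1L]] <- ch
      }
    }
    n$children <- out
    n
  }
  tnode_to_phylo(rec(nd))
}

#' Restrict a tree to a subset of its taxa
#'
#' Drops all other leaves and suppresses the resulting degree-two nodes
#' (their edge lengths are summed; the retained edge keeps the support of
#' its lower node).
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of leaf labels to keep (at least 2).
#' @return a `phylo` object on exactly `taxa`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  nd <- as_tnode(tree)
  have <- t_leaves(nd)
  missing <- setdiff(taxa, have)
  if (length(missing) > 0L) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa to keep")
  rec <- function(n) {
    if (t_is_leaf(n)) {
      if (n$label %in% taxa) return(n) else return(NULL)
    }
    kept <- Filter(Negate(is.null), lapply(n$children, rec))
    if (length(kept) == 0L) return(NULL)
    if (length(kept) == 1L) {
      ch <- kept[[1L]]
      if (!is.na(n$length)) {
        ch$length <- (if (is.na(ch$length)) 0 else ch$length) + n$length
      }
      return(ch)
    }
    n$children <- kept
    n
  }
  out <- rec(nd)
  out$length <- NA_real_
  out$support <- NA_real_
  tnode_to_phylo(out)
}

#' Prune two trees to their shared taxa
#'
#' Restricts both trees to the intersection of their leaf sets (taxa absent
#' from either side are dropped and reported via a message).
#'
#' @param t1,t2 `phylo` objects sharing at least 2 taxa.
#' @param quiet suppress the pruning message.
#' @return a list with the pruned trees (`t1`, `t2`), the `common` taxa,
#'   and the `dropped` ones.
#' @export
prune_to_common <- function(t1, t2, quiet = FALSE) {
  l1 <- as_phylo(t1)$tip.label
  l2 <- as_phylo(t2)$tip.label
  common <- intersect(l1, l2)
  if (length(common) < 2L) {
    stop("trees share fewer than 2 taxa")
  }
  dropped <- c(setdiff(l1, common), setdiff(l2, common))
  if (length(dropped) > 0L && !quiet) {
    message("pruned to ", length(common), " shared taxa (dropped: ",
            paste(sort(unique(dropped)), collapse = ", "), ")")
  }
  list(
    t1 = if (length(common) < length(l1)) prune_to_taxa(t1, common) else as_phylo(t1),
    t2 = if (length(common) < length(l2)) prune_to_taxa(t2, common) else as_phylo(t2),
    common = sort(common), dropped = sort(unique(dropped))
  )
}

# is every internal node strictly bifurcating?
is_binary_tree <- function(tree) t_is_binary(as_tnode(tree))
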