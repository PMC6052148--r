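# Error-aware topology fixing.  The statistical equivalence set of the
# likelihood-based fixers (paired-site tests over the alignment) is replaced
# by a bootstrap-support equivalence set: edges below the support threshold
# are negotiable, everything else is untouchable.  Negotiable edges are
# collapsed and the resulting polytomies re-resolved to minimise DTL
# reconciliation cost against the reference.

# --- polytomy machinery on tnodes ------------------------------------------

# paths (child-index vectors) of all nodes with > 2 children, in postorder
.polytomy_paths <- function(nd) {
  out <- list()
  rec <- function(n, path) {
    if (t_is_leaf(n)) return()
    for (i in seq_along(n$children)) rec(n$children[[i]], c(path, i))
    if (length(n$children) > 2L) out[[length(out) + 1L]] <<- path
  }
  rec(nd, integer(0))
  out
}

.node_at <- function(nd, path) {
  for (i in path) nd <- nd$children[[i]]
  nd
}

.replace_at <- function(nd, path, new) {
  if (length(path) == 0L) return(new)
  i <- path[1L]
  nd$children[[i]] <- .replace_at(nd$children[[i]], path[-1L], new)
  nd
}

# canonical order of subtrees: by smallest leaf label
.canon_order <- function(subtrees) {
  keys <- vapply(subtrees, function(s) min(t_leaves(s)), character(1L))
  subtrees[order(keys, method = "radix")]
}

# deterministic left-comb over canonically ordered children
.comb_resolve <- function(nd) {
  if (t_is_leaf(nd)) return(nd)
  nd$children <- lapply(nd$children, .comb_resolve)
  if (length(nd$children) > 2L) {
    ch <- .canon_order(nd$children)
    acc <- t_node(ch[1:2])
    for (j in seq_along(ch)[-(1:2)]) acc <- t_node(list(acc, ch[[j]]))
    nd$children <- acc$children
  }
  nd
}

# all rooted binary resolutions of a child list (sequential insertion;
# (2k-3)!! shapes, deterministic order)
.all_resolutions <- function(children) {
  children <- .canon_order(children)
  k <- length(children)
  if (k == 2L) return(list(children))
  insert_everywhere <- function(tree, sub) {
    res <- list(t_node(list(tree, sub)))
    if (!t_is_leaf(tree) && length(tree$children) == 2L &&
        is.null(attr(tree, "fixed_subtree"))) {
      for (i in 1:2) {
        for (alt in insert_everywhere(tree$children[[i]], sub)) {
          nn <- tree
          nn$children[[i]] <- alt
          res <- c(res, list(nn))
        }
      }
    }
    res
  }
  # mark the original child subtrees as atomic so insertion never descends
  # into them
  atoms <- lapply(children, function(s) {
    attr(s, "fixed_subtree") <- TRUE
    s
  })
  shapes <- list(t_node(atoms[1:2]))
  for (j in 3:k) {
    nxt <- list()
    for (tr in shapes) nxt <- c(nxt, insert_everywhere(tr, atoms[[j]]))
    shapes <- nxt
  }
  lapply(shapes, function(tr) list(tr$children[[1L]], tr$children[[2L]]))
}

.strip_atom_marks <- function(nd) {
  attr(nd, "fixed_subtree") <- NULL
  if (!t_is_leaf(nd)) nd$children <- lapply(nd$children, .strip_atom_marks)
  nd
}

# DTL cost of a (binary) tnode against the reference itree
.fix_cost <- function(nd, ref_phylo, costs) {
  dtl_reconcile(tnode_to_phylo(nd), ref_phylo, costs = costs)$cost
}

# choose the cost-minimal resolution of the polytomy at `path`, scoring each
# candidate as part of the full tree (any other polytomies comb-resolved)
.resolve_polytomy <- function(root, path, ref_phylo, costs,
                              exhaustive_limit = 6L) {
  node <- .node_at(root, path)
  children <- node$children
  k <- length(children)
  # score a fully resolved local subtree (a binary tnode over the original
  # child subtrees) as part of the whole tree
  score_resolved <- function(resolved) {
    nn <- node
    nn$children <- lapply(resolved$children, .strip_atom_marks)
    nn$support <- NA_real_
    cand <- .replace_at(root, path, nn)
    list(tree = cand, cost = .fix_cost(.comb_resolve(cand), ref_phylo, costs))
  }
  if (k <= exhaustive_limit) {
    best <- NULL
    for (two in .all_resolutions(children)) {
      sc <- score_resolved(t_node(two))
      if (is.null(best) || sc$cost < best$cost) best <- sc
    }
    best$tree
  } else {
    # greedy stepwise insertion: not-yet-inserted subtrees ride as a
    # canonical comb on top while each attachment point is scored
    ch <- .canon_order(children)
    atoms <- lapply(ch, function(s) {
      attr(s, "fixed_subtree") <- TRUE
      s
    })
    grow <- function(tree, sub) {
      res <- list(t_node(list(tree, sub)))
      if (!t_is_leaf(tree) && length(tree$children) == 2L &&
          is.null(attr(tree, "fixed_subtree"))) {
        for (i in 1:2) {
          for (alt in grow(tree$children[[i]], sub)) {
            nn <- tree
            nn$children[[i]] <- alt
            res <- c(res, list(nn))
          }
        }
      }
      res
    }
    local <- t_node(atoms[1:2])
    for (j in 3:k) {
      rest <- if (j < k) atoms[(j + 1L):k] else list()
      with_rest <- function(lt) {
        acc <- lt
        for (r in rest) acc <- t_node(list(acc, r))
        acc
      }
      best <- NULL
      for (cand in grow(local, atoms[[j]])) {
        sc <- score_resolved(with_rest(cand))
        if (is.null(best) || sc$cost < best$cost) {
          best <- list(cost = sc$cost, local = cand)
        }
      }
      local <- best$local
    }
    score_resolved(local)$tree
  }
}

#' Fix an associate tree against a reference
#'
#' Brings a gene or operon tree into agreement with a binary reference tree
#' wherever the associate's own bootstrap support does not contradict the
#' change: every internal edge with support strictly below
#' `support_threshold` is collapsed, and each resulting polytomy is
#' re-resolved to minimise the DTL reconciliation cost against the
#' reference — exhaustively over all rooted resolutions for polytomies with
#' up to 6 children (at most 945 candidates), by greedy stepwise insertion
#' above that.  Supported structure (support at or above the threshold) is
#' never altered, the tree is never re-rooted, and the DTL cost is never
#' worsened (the input is returned unchanged if no resolution improves on
#' it).
#'
#' @param assoc associate `phylo` tree (binary) with supports.
#' @param ref binary reference `phylo` tree.
#' @param support_threshold negotiability threshold in \[0, 100\]
#'   (default 70).
#' @param costs [dtl_costs()] scheme used for scoring (default 2-3-1).
#' @return an object of class `hot_fix`: `tree` (the fixed `phylo`),
#'   `removed` / `added` (bipartition keys changed), `cost_before`,
#'   `cost_after`, `threshold`.
#' @seealso [collapse_low_support()], [dtl_reconcile()]
#' @export
fix_tree <- function(assoc, ref, support_threshold = 70,
                     costs = dtl_costs()) {
  if (!is.numeric(support_threshold) || length(support_threshold) != 1L ||
      is.na(support_threshold) || support_threshold < 0 ||
      support_threshold > 100) {
    stop("support_threshold must be a single value in [0, 100]")
  }
  pr <- suppressMessages(prune_to_common(assoc, ref))
  ref_it <- as_itree(pr$t2)
  .require_binary_rooted(ref_it, "reference")
  assoc0 <- pr$t1
  binary_in <- is_binary_tree(assoc0)
  cost_before <- if (binary_in) {
    dtl_reconcile(assoc0, pr$t2, costs = costs)$cost
  } else {
    NA_real_
  }
  nd <- as_tnode(collapse_low_support(assoc0, support_threshold))
  # postorder: deepest polytomies first, so each node's children are binary
  # when its own resolution is chosen
  paths <- .polytomy_paths(nd)
  for (p in paths) nd <- .resolve_polytomy(nd, p, pr$t2, costs)
  fixed <- tnode_to_phylo(nd)
  cost_after <- dtl_reconcile(fixed, pr$t2, costs = costs)$cost
  if (binary_in && cost_after > cost_before) {
    fixed <- assoc0
    cost_after <- cost_before
  }
  b0 <- bipartition_set(assoc0)$split
  b1 <- bipartition_set(fixed)$split
  structure(list(
    tree = fixed,
    removed = setdiff(b0, b1),
    added = setdiff(b1, b0),
    cost_before = cost_before,
    cost_after = cost_after,
    threshold = support_threshold
  ), class = "hot_fix")
}

#' @export
print.hot_fix <- function(x, ...) {
  cat("tree fix (support threshold ", x$threshold, ")\n", sep = "")
  cat("  DTL cost: ", x$cost_before, " -> ", x$cost_after, "\n", sep = "")
  cat("  bipartitions removed: ", length(x$removed), ", added: ",
      length(x$added), "\n", sep = "")
  invisible(x)
}

#' Fix a set of gene trees against a common reference
#'
#' @inheritParams fix_tree
#' @param gene_trees named list of `phylo` trees.
#' @return a named list of `hot_fix` results with an attached
#'   `attr(,"n_changed")`, the total number of changed bipartitions.
#' @export
fix_all <- function(gene_trees, ref, support_threshold = 70,
                    costs = dtl_costs()) {
  if (!is.list(gene_trees) || length(gene_trees) == 0L) {
    stop("gene_trees must be a nonempty list")
  }
  out <- lapply(gene_trees, fix_tree, ref = ref,
                support_threshold = support_threshold, costs = costs)
  attr(out, "n_changed") <- sum(vapply(out, function(f) {
    length(f$removed) + length(f$added)
  }, 1L))
  out
}
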