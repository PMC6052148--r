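# Independent brute-force oracles and small-tree generators used across the
# suite.  The DTL oracle enumerates every mapping of internal gene nodes to
# species nodes; given a mapping, the cost of each node's event label is
# separable, so labels are minimised (and co-optimal labels counted) per
# node.  Nothing here shares code with the package's dynamic program.

# random rooted binary tree on the given labels (no lengths/supports)
random_rooted_tree <- function(labels) {
  nodes <- lapply(labels, function(l) hotrecon:::t_leaf(l))
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    joined <- hotrecon:::t_node(nodes[i])
    nodes <- c(nodes[-i], list(joined))
  }
  hotrecon:::tnode_to_phylo(nodes[[1L]])
}

# oracle: minimal undated DTL cost + number of co-optimal
# (mapping, event-label) assignments, by exhaustive enumeration
oracle_dtl <- function(gene, species, leaf_map = NULL, dup = 2, transfer = 3,
                       loss = 1) {
  gn <- hotrecon:::as_itree(gene)
  sp <- hotrecon:::as_itree(species)
  anc <- hotrecon:::itree_anc(sp)
  dn <- hotrecon:::itree_down_dist(sp, anc)
  incomp <- !anc & !t(anc)
  NS <- sp$n
  gtips <- which(gn$is_tip)
  if (is.null(leaf_map)) {
    leaf_map <- stats::setNames(gn$label[gtips], gn$label[gtips])
  }
  stip <- stats::setNames(which(sp$is_tip), sp$label[sp$is_tip])
  sigma <- integer(gn$n)
  for (v in gtips) sigma[v] <- stip[[leaf_map[[gn$label[v]]]]]
  internals <- which(!gn$is_tip)
  ni <- length(internals)

  # per (s, sa, sb): min label cost and number of label argmins
  node_cost <- function(s, sa, sb) {
    costs <- numeric(0)
    if (!sp$is_tip[s]) {
      k <- sp$children[[s]]
      if (anc[k[1L], sa] && anc[k[2L], sb]) {
        costs <- c(costs, loss * (dn[k[1L], sa] + dn[k[2L], sb]))
      }
      if (anc[k[1L], sb] && anc[k[2L], sa]) {
        costs <- c(costs, loss * (dn[k[1L], sb] + dn[k[2L], sa]))
      }
    }
    if (anc[s, sa] && anc[s, sb]) {
      costs <- c(costs, dup + loss * (dn[s, sa] + dn[s, sb]))
    }
    if (anc[s, sa] && incomp[s, sb]) {
      costs <- c(costs, transfer + loss * dn[s, sa])
    }
    if (anc[s, sb] && incomp[s, sa]) {
      costs <- c(costs, transfer + loss * dn[s, sb])
    }
    if (length(costs) == 0L) return(c(Inf, 0))
    m <- min(costs)
    c(m, sum(costs == m))
  }

  # precompute the (s, sa, sb) lookup
  CC <- array(Inf, c(NS, NS, NS))
  NN <- array(0, c(NS, NS, NS))
  for (s in seq_len(NS)) {
    for (sa in seq_len(NS)) {
      for (sb in seq_len(NS)) {
        r <- node_cost(s, sa, sb)
        CC[s, sa, sb] <- r[1L]
        NN[s, sa, sb] <- r[2L]
      }
    }
  }

  grids <- rep(list(seq_len(NS)), ni)
  M <- as.matrix(expand.grid(grids))
  colnames(M) <- NULL
  nmap <- nrow(M)
  full <- matrix(0L, nmap, gn$n)
  for (j in seq_along(internals)) full[, internals[j]] <- M[, j]
  for (v in gtips) full[, v] <- sigma[v]
  tot <- numeric(nmap)
  cnt <- rep(1, nmap)
  for (g in internals) {
    ch <- gn$children[[g]]
    idx <- cbind(full[, g], full[, ch[1L]], full[, ch[2L]])
    tot <- tot + CC[idx]
    cnt <- cnt * NN[idx]
  }
  m <- min(tot)
  list(cost = m, n_optimal = sum(cnt[tot == m & cnt > 0]))
}

# oracle: minimal Dollo loss count by exhaustive internal-state enumeration
# (root present; absence is hereditary — no regain)
oracle_dollo <- function(species, presence) {
  it <- hotrecon:::as_itree(species)
  internals <- setdiff(which(!it$is_tip), it$root)
  state <- rep(NA, it$n)          # TRUE = present
  state[it$root] <- TRUE
  for (v in which(it$is_tip)) state[v] <- presence[[it$label[v]]]
  k <- length(internals)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    s <- state
    if (k > 0L) {
      bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      s[internals] <- !bits        # bit set = absent
    }
    ok <- TRUE
    losses <- 0L
    for (v in seq_len(it$n)) {
      p <- it$parent[v]
      if (p == 0L) next
      if (!s[p] && s[v]) {          # regain: invalid under Dollo
        ok <- FALSE
        break
      }
      if (s[p] && !s[v]) losses <- losses + 1L
    }
    if (ok && losses < best) best <- losses
  }
  best
}

# brute-force compatibility of two bipartitions (the four intersections)
oracle_compatible <- function(b1, b2) {
  any(
    length(intersect(b1$side1, b2$side1)) == 0L,
    length(intersect(b1$side1, b2$side2)) == 0L,
    length(intersect(b1$side2, b2$side1)) == 0L,
    length(intersect(b1$side2, b2$side2)) == 0L
  )
}

# all rooted binary resolutions of a set of subtrees (as tnodes), generated
# by sequential insertion; the original subtrees are treated as atoms —
# insertion never descends into them.  Used to check fix_tree's exhaustive
# regime.  Count: (2k-3)!! for k subtrees.
all_resolutions <- function(subtrees) {
  atoms <- lapply(subtrees, function(s) {
    attr(s, "atom") <- TRUE
    s
  })
  strip <- function(nd) {
    attr(nd, "atom") <- NULL
    if (!hotrecon:::t_is_leaf(nd)) nd$children <- lapply(nd$children, strip)
    nd
  }
  if (length(atoms) == 1L) return(list(strip(atoms[[1L]])))
  insert_all <- function(tree, sub) {
    alts <- list(hotrecon:::t_node(list(tree, sub)))
    if (is.null(attr(tree, "atom")) && !hotrecon:::t_is_leaf(tree)) {
      for (i in 1:2) {
        for (alt in insert_all(tree$children[[i]], sub)) {
          nn <- tree
          nn$children[[i]] <- alt
          alts <- c(alts, list(nn))
        }
      }
    }
    alts
  }
  trees <- list(hotrecon:::t_node(atoms[1:2]))
  for (j in seq_along(atoms)[-(1:2)]) {
    nxt <- list()
    for (tr in trees) nxt <- c(nxt, insert_all(tr, atoms[[j]]))
    trees <- nxt
  }
  lapply(trees, strip)
}

# unrooted Robinson-Foulds distance via the package's bipartition sets
rf_dist <- function(t1, t2) {
  s1 <- bipartition_set(t1)$split
  s2 <- bipartition_set(t2)$split
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
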