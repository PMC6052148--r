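# Internal tree representations.
#
# Exported functions speak ape's "phylo". Two internal forms back them:
#   * "tnode": a recursive list (label, children, support, length) used for
#     tree surgery (collapsing, pruning, rerooting bookkeeping, NNI,
#     polytomy resolution), where editing ape's edge matrix is error prone.
#   * "itree": a flat indexed form (parent/children arrays, postorder) used
#     by the reconciliation dynamic programs.
# Supports live on internal edges only; the root never carries one.

t_leaf <- function(label, length = NA_real_) {
  list(label = label, children = list(), support = NA_real_, length = length)
}

t_node <- function(children, support = NA_real_, length = NA_real_,
                   label = NULL) {
  list(label = label, children = children, support = support, length = length)
}

t_is_leaf <- function(nd) length(nd$children) == 0L

t_leaves <- function(nd) {
  if (t_is_leaf(nd)) return(nd$label)
  unlist(lapply(nd$children, t_leaves), use.names = FALSE)
}

t_n_leaves <- function(nd) length(t_leaves(nd))

# TRUE when every internal node has exactly two children
t_is_binary <- function(nd) {
  if (t_is_leaf(nd)) return(TRUE)
  length(nd$children) == 2L && all(vapply(nd$children, t_is_binary, TRUE))
}

# numeric supports parsed from a phylo's node.label; NA where absent or
# non-numeric.  No rescaling here (read_newick owns the unit convention).
.parse_supports <- function(labels) {
  if (is.null(labels)) return(rep(NA_real_, 0L))
  sup <- suppressWarnings(as.numeric(labels))
  sup[!nzchar(trimws(ifelse(is.na(labels), "", labels)))] <- NA_real_
  sup
}

phylo_to_tnode <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  elen <- rep(NA_real_, nn)
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2L]] <- phy$edge.length
  nl <- phy$node.label
  sup <- if (!is.null(nl)) .parse_supports(nl) else rep(NA_real_, phy$Nnode)
  root <- nt + 1L
  build <- function(v) {
    if (v <= nt) return(t_leaf(phy$tip.label[v], elen[v]))
    ch <- lapply(kids[[v]], build)
    s <- sup[v - nt]
    lab <- NULL
    if (!is.null(nl)) {
      raw <- nl[v - nt]
      if (!is.na(raw) && nzchar(raw) && is.na(s)) lab <- raw
    }
    if (v == root) s <- NA_real_  # the root itself never carries a support
    t_node(ch, support = s, length = elen[v], label = lab)
  }
  build(root)
}

.nwk_quote <- function(lab) {
  if (grepl("[ ()\\[\\]:;,']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

.fmt_num <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

tnode_to_newick <- function(nd) {
  rec <- function(n) {
    if (t_is_leaf(n)) {
      s <- .nwk_quote(n$label)
    } else {
      inner <- paste(vapply(n$children, rec, character(1L)), collapse = ",")
      lab <- if (!is.na(n$support)) {
        .fmt_num(n$support)
      } else if (!is.null(n$label)) {
        .nwk_quote(n$label)
      } else {
        ""
      }
      s <- paste0("(", inner, ")", lab)
    }
    if (!is.na(n$length)) s <- paste0(s, ":", .fmt_num(n$length))
    s
  }
  paste0(rec(nd), ";")
}

tnode_to_phylo <- function(nd) {
  phy <- ape::read.tree(text = tnode_to_newick(nd))
  if (is.null(phy)) stop("internal error: failed to serialise tree")
  phy
}

# ---- indexed form ---------------------------------------------------------

as_tnode <- function(x) {
  if (inherits(x, "phylo")) return(phylo_to_tnode(x))
  if (is.list(x) && !is.null(x$children)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a tree")
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  tnode_to_phylo(as_tnode(x))
}

# Flatten to arrays.  Node ids are assigned in a deterministic preorder so
# identical input trees always index identically (tie-breaking relies on it).
as_itree <- function(x) {
  nd <- as_tnode(x)
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)
  env$children <- list()
  env$label <- character(0)
  env$support <- numeric(0)
  env$length <- numeric(0)
  env$is_tip <- logical(0)
  walk <- function(n, par) {
    id <- length(env$parent) + 1L
    env$parent[id] <- par
    env$children[[id]] <- integer(0)
    env$label[id] <- if (t_is_leaf(n)) n$label else NA_character_
    env$support[id] <- n$support
    env$length[id] <- n$length
    env$is_tip[id] <- t_is_leaf(n)
    if (par > 0L) env$children[[par]] <- c(env$children[[par]], id)
    for (ch in n$children) walk(ch, id)
    id
  }
  walk(nd, 0L)
  n <- length(env$parent)
  post <- integer(0)
  po <- function(v) {
    for (ch in env$children[[v]]) po(ch)
    post[[length(post) + 1L]] <<- v
  }
  po(1L)
  depth <- rep(NA_real_, n)
  depth[1L] <- 0
  for (v in rev(post)) {
    if (v != 1L) {
      l <- env$length[v]
      depth[v] <- depth[env$parent[v]] + (if (is.na(l)) 1 else l)
    }
  }
  structure(list(
    n = n, root = 1L, parent = env$parent, children = env$children,
    label = env$label, support = env$support, length = env$length,
    is_tip = env$is_tip, postorder = post, depth = depth,
    ntip = sum(env$is_tip)
  ), class = "hot_itree")
}

# tip label sets per node (list indexed by node id)
itree_clades <- function(it) {
  cl <- vector("list", it$n)
  for (v in it$postorder) {
    if (it$is_tip[v]) {
      cl[[v]] <- it$label[v]
    } else {
      cl[[v]] <- sort(unlist(cl[it$children[[v]]], use.names = FALSE))
    }
  }
  cl
}

# ancestor-or-equal matrix: anc[i, j] TRUE iff i lies on the root path of j
itree_anc <- function(it) {
  anc <- matrix(FALSE, it$n, it$n)
  for (v in rev(it$postorder)) {
    anc[v, v] <- TRUE
    p <- it$parent[v]
    if (p > 0L) anc[, v] <- anc[, v] | anc[, p]
  }
  anc
}

# edge-count distance from ancestor i down to descendant j (Inf otherwise)
itree_down_dist <- function(it, anc = itree_anc(it)) {
  lev <- integer(it$n)
  for (v in rev(it$postorder)) {
    p <- it$parent[v]
    lev[v] <- if (p > 0L) lev[p] + 1L else 0L
  }
  d <- matrix(Inf, it$n, it$n)
  for (i in seq_len(it$n)) {
    j <- which(anc[i, ])
    d[i, j] <- lev[j] - lev[i]
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
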