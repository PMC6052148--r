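#' Duplication-transfer-loss cost scheme
#'
#' The default costs (duplication 2, transfer 3, loss 1) are the scheme used
#' throughout the horizontal-operon-transfer analysis; they match the default
#' cost matrix of the TreeFix-DTL / NOTUNG tool family.
#'
#' @param dup,transfer,loss non-negative event costs.
#' @return an object of class `dtl_costs`.
#' @export
dtl_costs <- function(dup = 2, transfer = 3, loss = 1) {
  for (v in c(dup, transfer, loss)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("all DTL costs must be single non-negative numbers")
    }
  }
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "dtl_costs")
}

# resolve the gene-leaf -> species-leaf mapping into species node ids
.resolve_leaf_map <- function(gn, sp, leaf_map) {
  gtips <- gn$label[gn$is_tip]
  stips <- sp$label[sp$is_tip]
  if (is.null(leaf_map)) {
    leaf_map <- stats::setNames(gtips, gtips)
  }
  if (is.null(names(leaf_map))) {
    stop("leaf_map must be a named character vector (gene leaf -> species leaf)")
  }
  miss <- setdiff(gtips, names(leaf_map))
  if (length(miss) > 0L) {
    stop("gene leaves absent from the leaf map: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unname(leaf_map[gtips]), stips)
  if (length(bad) > 0L) {
    stop("leaf map targets absent from the species tree: ",
         paste(unique(bad), collapse = ", "))
  }
  sid <- stats::setNames(which(sp$is_tip), sp$label[sp$is_tip])
  out <- integer(gn$n)
  for (v in which(gn$is_tip)) out[v] <- sid[[leaf_map[[gn$label[v]]]]]
  out
}

.require_binary_rooted <- function(it, what) {
  for (v in seq_len(it$n)) {
    if (!it$is_tip[v] && length(it$children[[v]]) != 2L) {
      stop(what, " tree must be binary and rooted; node with ",
           length(it$children[[v]]), " children found. ",
           "Resolve polytomies first (see fix_tree()).")
    }
  }
  invisible(TRUE)
}

# Dynamic program over (gene node, species node).
#   C[g,s]   minimal cost of the subtree of g when g is mapped to s
#   IN[g,s]  min over descendants s'' of s of C[g,s''] + loss * dist(s,s'')
#   OUT[g,s] min over species nodes incomparable to s of C[g,s']
# plus exact co-optimal counts (NC/NIN/NOUT) summed over tied alternatives
# and multiplied over independent children.
.dtl_tables <- function(gn, sp, sigma, costs) {
  NS <- sp$n
  NG <- gn$n
  Dc <- costs$dup
  Tc <- costs$transfer
  Lc <- costs$loss
  k1 <- rep(NA_integer_, NS)
  k2 <- rep(NA_integer_, NS)
  for (s in seq_len(NS)) {
    if (!sp$is_tip[s]) {
      k1[s] <- sp$children[[s]][1L]
      k2[s] <- sp$children[[s]][2L]
    }
  }
  sint <- which(!sp$is_tip)
  spo <- sp$postorder
  spre <- rev(spo)
  C <- matrix(Inf, NG, NS)
  NC <- matrix(0, NG, NS)
  IN <- matrix(Inf, NG, NS)
  NIN <- matrix(0, NG, NS)
  OUT <- matrix(Inf, NG, NS)
  NOUT <- matrix(0, NG, NS)

  for (g in gn$postorder) {
    if (gn$is_tip[g]) {
      C[g, sigma[g]] <- 0
      NC[g, sigma[g]] <- 1
    } else {
      ch <- gn$children[[g]]
      a <- ch[1L]
      b <- ch[2L]
      INa <- IN[a, ]; INb <- IN[b, ]
      NINa <- NIN[a, ]; NINb <- NIN[b, ]
      OUTa <- OUT[a, ]; OUTb <- OUT[b, ]
      NOUTa <- NOUT[a, ]; NOUTb <- NOUT[b, ]
      dup <- Dc + INa + INb
      tr1 <- Tc + INa + OUTb   # a kept in s, b transferred
      tr2 <- Tc + INb + OUTa
      sp1 <- rep(Inf, NS)
      sp2 <- rep(Inf, NS)
      sp1[sint] <- INa[k1[sint]] + INb[k2[sint]]
      sp2[sint] <- INa[k2[sint]] + INb[k1[sint]]
      Cg <- pmin(sp1, sp2, dup, tr1, tr2)
      cnt <- rep(0, NS)
      fin <- is.finite(Cg)
      nsp1 <- rep(0, NS); nsp1[sint] <- NINa[k1[sint]] * NINb[k2[sint]]
      nsp2 <- rep(0, NS); nsp2[sint] <- NINa[k2[sint]] * NINb[k1[sint]]
      cnt[fin & sp1 == Cg] <- cnt[fin & sp1 == Cg] + nsp1[fin & sp1 == Cg]
      cnt[fin & sp2 == Cg] <- cnt[fin & sp2 == Cg] + nsp2[fin & sp2 == Cg]
      idx <- fin & dup == Cg
      cnt[idx] <- cnt[idx] + NINa[idx] * NINb[idx]
      idx <- fin & tr1 == Cg
      cnt[idx] <- cnt[idx] + NINa[idx] * NOUTb[idx]
      idx <- fin & tr2 == Cg
      cnt[idx] <- cnt[idx] + NINb[idx] * NOUTa[idx]
      C[g, ] <- Cg
      NC[g, ] <- cnt
    }
    # IN / NIN by species postorder
    inv <- C[g, ]
    ninv <- NC[g, ]
    for (s in spo) {
      if (!sp$is_tip[s]) {
        cands <- c(inv[s], Lc + inv[k1[s]], Lc + inv[k2[s]])
        m <- min(cands)
        if (is.finite(m)) {
          n <- 0
          if (cands[1L] == m) n <- n + ninv[s]
          if (cands[2L] == m) n <- n + ninv[k1[s]]
          if (cands[3L] == m) n <- n + ninv[k2[s]]
          inv[s] <- m
          ninv[s] <- n
        }
      }
    }
    IN[g, ] <- inv
    NIN[g, ] <- ninv
    # subtree-minimum of C (no loss charge), then OUT by preorder
    bv <- C[g, ]
    nbv <- NC[g, ]
    for (s in spo) {
      if (!sp$is_tip[s]) {
        cands <- c(bv[s], bv[k1[s]], bv[k2[s]])
        m <- min(cands)
        if (is.finite(m)) {
          n <- 0
          if (cands[1L] == m) n <- n + nbv[s]
          if (cands[2L] == m) n <- n + nbv[k1[s]]
          if (cands[3L] == m) n <- n + nbv[k2[s]]
          bv[s] <- m
          nbv[s] <- n
        }
      }
    }
    ov <- rep(Inf, NS)
    nov <- rep(0, NS)
    for (s in spre) {
      if (!sp$is_tip[s]) {
        for (which_child in 1:2) {
          v <- if (which_child == 1L) k1[s] else k2[s]
          w <- if (which_child == 1L) k2[s] else k1[s]
          m <- min(ov[s], bv[w])
          n <- 0
          if (is.finite(m)) {
            if (ov[s] == m) n <- n + nov[s]
            if (bv[w] == m) n <- n + nbv[w]
          }
          ov[v] <- m
          nov[v] <- n
        }
      }
    }
    OUT[g, ] <- ov
    NOUT[g, ] <- nov
  }
  list(C = C, NC = NC, IN = IN, NIN = NIN, OUT = OUT, NOUT = NOUT,
       k1 = k1, k2 = k2, sigma = sigma, costs = costs)
}

# human-readable node names: tip labels for tips, "n<i>" plus clade hint
# for internal nodes
.node_names <- function(it) {
  cl <- itree_clades(it)
  nm <- character(it$n)
  for (v in seq_len(it$n)) {
    nm[v] <- if (it$is_tip[v]) {
      it$label[v]
    } else {
      paste0("mrca(", cl[[v]][1L], "+", cl[[v]][length(cl[[v]])], ")")
    }
  }
  nm
}

# --- scenario reconstruction ------------------------------------------------
# Options at each table entry are re-derived from the stored tables, either
# picking the first option in the deterministic priority order (speciation >
# duplication > transfer; smaller species index first) or enumerating all of
# them up to a limit.

.scen_new <- function() list(events = list(), mapping = integer(0))

.scen_merge <- function(a, b) {
  list(events = c(a$events, b$events), mapping = c(a$mapping, b$mapping))
}

# cross product of scenario lists, capped
.scen_cross <- function(las, lbs, limit) {
  out <- list()
  for (a in las) {
    for (b in lbs) {
      out[[length(out) + 1L]] <- .scen_merge(a, b)
      if (length(out) >= limit) return(out)
    }
  }
  out
}

# all descent paths from s achieving IN[g,s]; each yields (placement, losses)
.in_paths <- function(tb, gn, sp, g, s, limit) {
  res <- list()
  walk <- function(cur, losses) {
    if (length(res) >= limit) return()
    inval <- tb$IN[g, cur]
    if (tb$C[g, cur] == inval) {
      res[[length(res) + 1L]] <<- list(place = cur, losses = losses)
    }
    if (!sp$is_tip[cur]) {
      for (which_child in 1:2) {
        k <- if (which_child == 1L) tb$k1[cur] else tb$k2[cur]
        sib <- if (which_child == 1L) tb$k2[cur] else tb$k1[cur]
        if (is.finite(tb$IN[g, k]) &&
            tb$costs$loss + tb$IN[g, k] == inval) {
          walk(k, c(losses, sib))
        }
      }
    }
  }
  if (is.finite(tb$IN[g, s])) walk(s, integer(0))
  res
}

# scenarios for the subtree of gene node g mapped (C-level) at species s
.c_scenarios <- function(tb, gn, sp, g, s, limit, first_only) {
  if (gn$is_tip[g]) {
    sc <- .scen_new()
    sc$mapping <- stats::setNames(s, as.character(g))
    return(list(sc))
  }
  ch <- gn$children[[g]]
  a <- ch[1L]
  b <- ch[2L]
  target <- tb$C[g, s]
  Dc <- tb$costs$dup
  Tc <- tb$costs$transfer
  out <- list()
  cap <- function() length(out) >= limit
  emit_pair <- function(kind, e_extra, ga, sa_mode, gb, sb_mode) {
    # sa_mode/sb_mode: list(type = "in"/"c", s = node)
    sub <- function(gg, mode) {
      if (mode$type == "in") {
        paths <- .in_paths(tb, gn, sp, gg, mode$s, if (first_only) 1L else limit)
        res <- list()
        for (p in paths) {
          for (inner in .c_scenarios(tb, gn, sp, gg, p$place, limit,
                                     first_only)) {
            sc <- inner
            for (l in p$losses) {
              sc$events[[length(sc$events) + 1L]] <-
                list(kind = "loss", gene = NA_integer_, species = l,
                     donor = NA_integer_, recipient = NA_integer_)
            }
            res[[length(res) + 1L]] <- sc
            if (first_only && length(res) >= 1L) return(res)
            if (length(res) >= limit) return(res)
          }
        }
        res
      } else {
        .c_scenarios(tb, gn, sp, gg, mode$s, limit, first_only)
      }
    }
    la <- sub(ga, sa_mode)
    lb <- sub(gb, sb_mode)
    combined <- .scen_cross(la, lb, limit - length(out))
    for (sc in combined) {
      sc$events[[length(sc$events) + 1L]] <- e_extra
      sc$mapping <- c(sc$mapping, stats::setNames(s, as.character(g)))
      out[[length(out) + 1L]] <<- sc
      if (cap()) break
    }
  }
  # speciation (both orientations), in deterministic order
  if (!sp$is_tip[s]) {
    s1 <- tb$k1[s]
    s2 <- tb$k2[s]
    for (orient in 1:2) {
      if (cap() || (first_only && length(out) > 0L)) break
      ca <- if (orient == 1L) s1 else s2
      cb <- if (orient == 1L) s2 else s1
      v <- tb$IN[a, ca] + tb$IN[b, cb]
      if (is.finite(v) && v == target) {
        emit_pair("speciation",
                  list(kind = "speciation", gene = g, species = s,
                       donor = NA_integer_, recipient = NA_integer_),
                  a, list(type = "in", s = ca), b, list(type = "in", s = cb))
      }
    }
  }
  # duplication
  if (!(first_only && length(out) > 0L) && !cap()) {
    v <- Dc + tb$IN[a, s] + tb$IN[b, s]
    if (is.finite(v) && v == target) {
      emit_pair("duplication",
                list(kind = "duplication", gene = g, species = s,
                     donor = NA_integer_, recipient = NA_integer_),
                a, list(type = "in", s = s), b, list(type = "in", s = s))
    }
  }
  # transfer: kept child stays under s, moved child arrives at an
  # incomparable species node (smallest index first)
  if (!(first_only && length(out) > 0L) && !cap()) {
    anc <- attr(tb, "anc")
    for (orient in 1:2) {
      if (cap() || (first_only && length(out) > 0L)) break
      keep <- if (orient == 1L) a else b
      move <- if (orient == 1L) b else a
      v <- Tc + tb$IN[keep, s] + tb$OUT[move, s]
      if (is.finite(v) && v == target) {
        recips <- which(!anc[s, ] & !anc[, s] &
                          tb$C[move, ] == tb$OUT[move, s])
        for (r in recips) {
          if (cap() || (first_only && length(out) > 0L)) break
          emit_pair("transfer",
                    list(kind = "transfer", gene = g, species = s,
                         donor = s, recipient = r),
                    keep, list(type = "in", s = s),
                    move, list(type = "c", s = r))
        }
      }
    }
  }
  out
}

.scen_to_events <- function(sc, gnames, snames) {
  if (length(sc$events) == 0L) {
    ev <- data.frame(kind = character(0), gene_node = character(0),
                     species_node = character(0), donor = character(0),
                     recipient = character(0), stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, lapply(sc$events, function(e) {
      data.frame(
        kind = e$kind,
        gene_node = if (is.na(e$gene)) NA_character_ else gnames[e$gene],
        species_node = snames[e$species],
        donor = if (is.na(e$donor)) NA_character_ else snames[e$donor],
        recipient = if (is.na(e$recipient)) NA_character_ else
          snames[e$recipient],
        stringsAsFactors = FALSE
      )
    }))
  }
  # speciation rows are bookkeeping of agreement; order events canonically
  ev[order(match(ev$kind, c("speciation", "duplication", "transfer", "loss")),
           ev$species_node, ev$gene_node, method = "radix"), , drop = FALSE]
}

# heuristic screen for time-inconsistent transfer sets: transfer A must
# precede B when A's recipient edge is a strict ancestor of B's donor or
# recipient edge; a cycle in that precedence digraph flags the scenario
.transfers_time_consistent <- function(ev_idx, anc) {
  tr <- Filter(function(e) e$kind == "transfer", ev_idx)
  k <- length(tr)
  if (k < 2L) return(TRUE)
  strict_anc <- function(i, j) i != j && anc[i, j]
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (strict_anc(tr[[i]]$recipient, tr[[j]]$donor) ||
          strict_anc(tr[[i]]$recipient, tr[[j]]$recipient)) {
        adj[i, j] <- TRUE
      }
    }
  }
  # cycle detection by DFS colouring
  state <- integer(k)
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    state[v] <<- 1L
    for (w in which(adj[v, ])) {
      if (state[w] == 1L) {
        ok <<- FALSE
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
  }
  for (v in seq_len(k)) if (state[v] == 0L) visit(v)
  ok
}

#' Undated DTL maximum-parsimony reconciliation
#'
#' Reconciles a rooted binary gene (or operon) tree with a rooted binary
#' species tree under the undated duplication-transfer-loss parsimony model.
#' Internal gene nodes are mapped to species nodes and labelled as
#' speciations, duplications, or transfers; transfers connect incomparable
#' species edges (neither ancestral to the other); losses are charged for
#' every species edge a gene lineage crosses without an accounted
#' descendant.  The gene root may map anywhere without loss charges above
#' it.  One optimal scenario is reported with deterministic tie-breaking
#' (speciation preferred over duplication over transfer; smallest species
#' node index among tied choices) and the exact number of co-optimal
#' (mapping, event-label) assignments is counted by a companion counting
#' program.
#'
#' @param gene rooted binary `phylo` gene/operon tree.
#' @param species rooted binary `phylo` species tree.
#' @param leaf_map named character vector mapping gene leaf labels to species
#'   leaf labels; `NULL` (default) uses the identity on shared labels.
#' @param costs a [dtl_costs()] scheme (default 2-3-1).
#' @return an object of class `dtl_reconciliation`: `cost`, `n_optimal`,
#'   `events` (data frame: kind, gene_node, species_node, donor, recipient),
#'   `summary` (event counts), `root_location`, `time_consistent` (heuristic
#'   cycle screen over the reported transfers; `FALSE` only warns — global
#'   time consistency is not part of the undated model), and `costs`.
#' @examples
#' sp <- read_newick(text = "((A,B),C);")
#' gn <- read_newick(text = "((A,C),B);")
#' rec <- dtl_reconcile(gn, sp)
#' rec$cost          # 3: one transfer
#' event_summary(rec)
#' @seealso [enumerate_scenarios()], [event_summary()], [dollo_loss_count()]
#' @export
dtl_reconcile <- function(gene, species, leaf_map = NULL,
                          costs = dtl_costs()) {
  stopifnot(inherits(costs, "dtl_costs"))
  gn <- as_itree(gene)
  sp <- as_itree(species)
  .require_binary_rooted(sp, "species")
  .require_binary_rooted(gn, "gene")
  sigma <- .resolve_leaf_map(gn, sp, leaf_map)
  tb <- .dtl_tables(gn, sp, sigma, costs)
  anc <- itree_anc(sp)
  attr(tb, "anc") <- anc
  groot <- gn$root
  total <- min(tb$C[groot, ])
  if (!is.finite(total)) stop("no feasible reconciliation (internal error)")
  roots <- which(tb$C[groot, ] == total)
  n_opt <- sum(tb$NC[groot, roots])
  s0 <- roots[1L]
  sc <- .c_scenarios(tb, gn, sp, groot, s0, limit = 1L, first_only = TRUE)[[1L]]
  gnames <- .node_names(gn)
  snames <- .node_names(sp)
  ev <- .scen_to_events(sc, gnames, snames)
  cnt <- c(
    speciations = sum(ev$kind == "speciation"),
    duplications = sum(ev$kind == "duplication"),
    transfers = sum(ev$kind == "transfer"),
    losses = sum(ev$kind == "loss")
  )
  tc <- .transfers_time_consistent(sc$events, anc)
  mapping <- stats::setNames(snames[sc$mapping],
                             gnames[as.integer(names(sc$mapping))])
  structure(list(
    cost = total, n_optimal = n_opt, events = ev, summary = cnt,
    mapping = mapping[order(names(mapping), method = "radix")],
    root_location = snames[s0], time_consistent = tc, costs = costs
  ), class = "dtl_reconciliation")
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  cat("DTL reconciliation (costs ", x$costs$dup, "-", x$costs$transfer, "-",
      x$costs$loss, ")\n", sep = "")
  cat("  cost:", x$cost, " co-optimal scenarios:", format(x$n_optimal), "\n")
  cat("  events:", paste(names(x$summary), x$summary, collapse = ", "), "\n")
  if (!isTRUE(x$time_consistent)) {
    cat("  note: reported transfers fail the heuristic time-order screen\n")
  }
  invisible(x)
}

#' Enumerate co-optimal DTL reconciliation scenarios
#'
#' Exhaustive backtracking over the co-optimal choices of the reconciliation
#' dynamic program.  When the number of co-optimal scenarios does not exceed
#' `limit`, the returned list has exactly `n_optimal` elements; the first
#' element is the same scenario that [dtl_reconcile()] reports.
#'
#' @inheritParams dtl_reconcile
#' @param limit maximum number of scenarios to return (>= 1).
#' @return a list of scenarios; each has `events` (data frame) and `mapping`
#'   (named character: gene node -> species node).  `attr(,"n_optimal")` and
#'   `attr(,"cost")` carry the DP totals.
#' @export
enumerate_scenarios <- function(gene, species, leaf_map = NULL,
                                costs = dtl_costs(), limit = 100L) {
  if (!is.numeric(limit) || length(limit) != 1L || is.na(limit) || limit < 1) {
    stop("limit must be >= 1")
  }
  limit <- as.integer(limit)
  gn <- as_itree(gene)
  sp <- as_itree(species)
  .require_binary_rooted(sp, "species")
  .require_binary_rooted(gn, "gene")
  sigma <- .resolve_leaf_map(gn, sp, leaf_map)
  tb <- .dtl_tables(gn, sp, sigma, costs)
  anc <- itree_anc(sp)
  attr(tb, "anc") <- anc
  groot <- gn$root
  total <- min(tb$C[groot, ])
  roots <- which(tb$C[groot, ] == total)
  gnames <- .node_names(gn)
  snames <- .node_names(sp)
  out <- list()
  for (s0 in roots) {
    if (length(out) >= limit) break
    for (sc in .c_scenarios(tb, gn, sp, groot, s0,
                            limit = limit - length(out), first_only = FALSE)) {
      mapping <- stats::setNames(snames[sc$mapping],
                                 gnames[as.integer(names(sc$mapping))])
      out[[length(out) + 1L]] <- list(
        events = .scen_to_events(sc, gnames, snames),
        mapping = mapping[order(names(mapping), method = "radix")]
      )
      if (length(out) >= limit) break
    }
  }
  attr(out, "cost") <- total
  attr(out, "n_optimal") <- sum(tb$NC[groot, roots])
  out
}

#' Event counts of a reconciliation
#'
#' @param rec a `dtl_reconciliation` object.
#' @return named integer vector: speciations, duplications, transfers,
#'   losses.  The identity `cost = dup*duplications + transfer*transfers +
#'   loss*losses` holds for the reported scenario.
#' @export
event_summary <- function(rec) {
  stopifnot(inherits(rec, "dtl_reconciliation"))
  rec$summary
}

#' Minimal loss count under a single-origin (Dollo) model
#'
#' Under the vertical-inheritance null hypothesis the operon is present at
#' the species root, is never regained, and its scattered extant
#' distribution must be explained purely by losses.  The minimal number of
#' present-to-absent transitions equals the number of maximal all-absent
#' clades; the returned loss edges are the stem edges of those clades.
#'
#' @param species a rooted `phylo` species tree.
#' @param presence leaf presence/absence: a named logical vector over all
#'   leaves, or a two-column data frame (taxon, present).
#' @return a list with `n_losses` and `loss_edges`, a data frame giving for
#'   each loss the stem node, clade size, and clade tips (comma-joined).
#' @examples
#' sp <- read_newick(text = "((A,B),(C,D));")
#' dollo_loss_count(sp, c(A = TRUE, B = TRUE, C = FALSE, D = FALSE))
#' @export
dollo_loss_count <- function(species, presence) {
  it <- as_itree(species)
  tips <- it$label[it$is_tip]
  if (is.data.frame(presence)) {
    presence <- stats::setNames(as.logical(presence[[2L]]),
                                as.character(presence[[1L]]))
  }
  if (is.null(names(presence))) {
    stop("presence must be named by leaf label")
  }
  unknown <- setdiff(names(presence), tips)
  if (length(unknown) > 0L) {
    stop("unknown leaf label(s) in presence table: ",
         paste(unknown, collapse = ", "))
  }
  miss <- setdiff(tips, names(presence))
  if (length(miss) > 0L) {
    stop("presence missing for leaf label(s): ", paste(miss, collapse = ", "))
  }
  absent <- rep(FALSE, it$n)
  for (v in it$postorder) {
    absent[v] <- if (it$is_tip[v]) {
      !presence[[it$label[v]]]
    } else {
      all(absent[it$children[[v]]])
    }
  }
  absent[it$root] <- FALSE  # root state is present by model assumption
  stems <- which(vapply(seq_len(it$n), function(v) {
    v != it$root && absent[v] && !absent[it$parent[v]]
  }, TRUE))
  cl <- itree_clades(it)
  snames <- .node_names(it)
  loss_edges <- data.frame(
    node = snames[stems],
    clade_size = vapply(stems, function(v) length(cl[[v]]), 1L),
    tips = vapply(stems, function(v) paste(cl[[v]], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  loss_edges <- loss_edges[order(loss_edges$tips, method = "radix"), ,
                           drop = FALSE]
  rownames(loss_edges) <- NULL
  list(n_losses = length(stems), loss_edges = loss_edges)
}
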