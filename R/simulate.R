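# Synthetic operon-evolution generator.
#
# The generator works at topology level: an ultrametric species tree, an
# operon copy genealogy evolving on it by vertical descent, horizontal
# operon transfer (a timed subtree-prune-regraft with replacement of the
# recipient's copy) and loss (lineage-terminal, Dollo-like), per-gene
# transfers within the operon, and a direct bootstrap-support model.
# Sequence evolution is not simulated — every downstream stage consumes
# trees plus supports only.

#' Simulate an ultrametric Yule species tree
#'
#' @param n number of tips (>= 2).
#' @param birth_rate Yule birth rate (per lineage per unit time; default 1,
#'   giving an expected total branch length of (n-1)/birth_rate).
#' @param seed optional integer seed; the tree is fully determined by it.
#' @return an ultrametric `phylo` tree with tips `s01..sNN`.
#' @export
simulate_species_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("n must be an integer >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n, birth = birth_rate, death = 0)
  phy$tip.label <- sprintf("s%02d", seq_len(n))
  phy$node.label <- NULL
  phy
}

.check_ultrametric <- function(it) {
  td <- it$depth[it$is_tip]
  tol <- 1e-6 * max(td, 1e-12)
  if (max(td) - min(td) > tol) {
    stop("tree must be ultrametric (equal root-to-tip path lengths)")
  }
  max(td)
}

# Replay a timed event list on the species tree and build the copy
# genealogy.  Events: data frame (time, type in "transfer"/"loss", donor,
# recipient) with donor/recipient = species node ids (the edge above that
# node).  Deterministic.  Returns the surviving-copy tree (tnode or NULL if
# < 1 survivor), the presence vector, and per-edge carrier intervals.
.replay_genealogy <- function(it, events) {
  T_end <- .check_ultrametric(it)
  n <- it$n
  # speciation schedule: internal nodes (except acting on the root first)
  internals <- setdiff(which(!it$is_tip), it$root)
  timeline <- data.frame(
    time = c(it$depth[internals], events$time),
    kind = c(rep("speciation", length(internals)),
             as.character(events$type)),
    node = c(internals, events$donor),
    recipient = c(rep(NA_integer_, length(internals)), events$recipient),
    stringsAsFactors = FALSE
  )
  timeline <- timeline[order(timeline$time,
                             match(timeline$kind,
                                   c("speciation", "loss", "transfer"))), ,
                       drop = FALSE]
  cp_parent <- integer(0)
  cp_birth <- numeric(0)
  cp_kids <- list()
  new_copy <- function(parent, t) {
    id <- length(cp_parent) + 1L
    cp_parent[id] <<- parent
    cp_birth[id] <<- t
    cp_kids[[id]] <<- integer(0)
    if (parent > 0L) cp_kids[[parent]] <<- c(cp_kids[[parent]], id)
    id
  }
  active <- rep(NA_integer_, n)   # copy id per active carrier edge
  carrier <- rep(FALSE, n)
  alive <- rep(FALSE, n)          # edge currently spans the sweep time
  # carrier intervals (for per-gene transfer exposure)
  iv_edge <- integer(0)
  iv_from <- numeric(0)
  iv_to <- numeric(0)
  carr_since <- rep(NA_real_, n)
  start_carry <- function(e, t) carr_since[e] <<- t
  stop_carry <- function(e, t) {
    iv_edge[length(iv_edge) + 1L] <<- e
    iv_from[length(iv_from) + 1L] <<- carr_since[e]
    iv_to[length(iv_to) + 1L] <<- t
    carr_since[e] <<- NA_real_
  }
  root_copy <- new_copy(0L, it$depth[it$root])
  for (ch in it$children[[it$root]]) {
    alive[ch] <- TRUE
    carrier[ch] <- TRUE
    active[ch] <- new_copy(root_copy, it$depth[it$root])
    start_carry(ch, it$depth[it$root])
  }
  for (i in seq_len(nrow(timeline))) {
    t <- timeline$time[i]
    kind <- timeline$kind[i]
    v <- timeline$node[i]
    if (kind == "speciation") {
      if (carrier[v]) {
        stop_carry(v, t)
        for (ch in it$children[[v]]) {
          carrier[ch] <- TRUE
          active[ch] <- new_copy(active[v], t)
          start_carry(ch, t)
        }
      }
      for (ch in it$children[[v]]) alive[ch] <- TRUE
      alive[v] <- FALSE
      carrier[v] <- FALSE
      active[v] <- NA_integer_
    } else if (kind == "loss") {
      if (!alive[v] || !carrier[v]) {
        stop("loss event on a non-carrier or inactive lineage (node ", v,
             " at time ", signif(t, 4), ")")
      }
      stop_carry(v, t)
      carrier[v] <- FALSE
      active[v] <- NA_integer_
    } else {  # transfer
      r <- timeline$recipient[i]
      if (!alive[v] || !carrier[v]) {
        stop("transfer from a non-carrier or inactive donor (node ", v,
             " at time ", signif(t, 4), ")")
      }
      if (!alive[r]) {
        stop("transfer to an inactive recipient (node ", r, " at time ",
             signif(t, 4), ")")
      }
      donor_copy <- active[v]
      active[v] <- new_copy(donor_copy, t)
      if (carrier[r]) stop_carry(r, t)  # displaced copy dies
      active[r] <- new_copy(donor_copy, t)
      if (!carrier[r]) {
        carrier[r] <- TRUE
        start_carry(r, t)
      } else {
        start_carry(r, t)
      }
    }
  }
  tips <- which(it$is_tip)
  for (e in tips) if (carrier[e]) stop_carry(e, T_end)
  presence <- stats::setNames(vapply(tips, function(e) {
    !is.na(active[e])
  }, TRUE), it$label[tips])
  surv_label <- rep(NA_character_, length(cp_parent))
  for (e in tips) {
    if (!is.na(active[e])) surv_label[active[e]] <- it$label[e]
  }
  build <- function(c_id) {
    kids <- cp_kids[[c_id]]
    if (length(kids) == 0L) {
      if (is.na(surv_label[c_id])) return(NULL)
      return(list(node = t_leaf(surv_label[c_id]), time = T_end))
    }
    parts <- Filter(Negate(is.null), lapply(kids, build))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    t_split <- cp_birth[kids[1L]]
    ch <- lapply(parts, function(p) {
      nd <- p$node
      nd$length <- p$time - t_split
      nd
    })
    list(node = t_node(ch), time = t_split)
  }
  res <- build(root_copy)
  operon <- NULL
  if (!is.null(res) && !t_is_leaf(res$node)) {
    operon <- tnode_to_phylo(res$node)
  }
  list(
    operon = operon,
    presence = presence,
    carrier_intervals = data.frame(edge = iv_edge, from = iv_from,
                                   to = iv_to)
  )
}

# carriers whose interval covers time t
.carriers_at <- function(intervals, t) {
  unique(intervals$edge[intervals$from <= t & intervals$to > t])
}

#' Simulate the history of an operon on a species tree
#'
#' Forward-in-time sweep: the operon is present at the root; on each
#' carrier lineage, losses arrive at rate `loss_rate` (the lineage stops
#' carrying — no regain except by transfer) and transfers at rate
#' `hot_rate`.  A transfer's recipient is drawn uniformly among the other
#' contemporaneous lineages; the recipient becomes (or remains) a carrier
#' and its operon lineage is replaced by the donor's — one timed
#' subtree-prune-regraft on the operon genealogy.  The true operon tree is
#' the species tree transformed by the surviving SPRs and pruned to carrier
#' tips.
#'
#' @param tree ultrametric `phylo` species tree.
#' @param hot_rate horizontal operon transfer rate (per carrier lineage per
#'   unit time).
#' @param loss_rate operon loss rate (same units).
#' @param seed optional integer seed; the whole history is determined by it.
#' @return an object of class `operon_history`: `species_tree`, `events`
#'   (data frame: time, type, donor, recipient — node ids of the species
#'   tree in [node_id()] indexing, with readable labels alongside),
#'   `presence` (named logical over tips), `operon_tree` (`phylo`, or
#'   `NULL` if fewer than 2 carriers survive), `carrier_intervals`, and the
#'   realised `n_transfers` / `n_losses`.
#' @seealso [simulate_gene_trees()], [simulate_planted_hots()]
#' @export
simulate_operon_history <- function(tree, hot_rate, loss_rate, seed = NULL) {
  if (hot_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  it <- as_itree(tree)
  .require_binary_rooted(it, "species")
  T_end <- .check_ultrametric(it)
  internals <- setdiff(which(!it$is_tip), it$root)
  sched <- internals[order(it$depth[internals])]
  alive <- rep(FALSE, it$n)
  carrier <- rep(FALSE, it$n)
  for (ch in it$children[[it$root]]) {
    alive[ch] <- TRUE
    carrier[ch] <- TRUE
  }
  ev_time <- numeric(0)
  ev_type <- character(0)
  ev_donor <- integer(0)
  ev_recip <- integer(0)
  t_now <- it$depth[it$root]
  total_rate <- hot_rate + loss_rate
  next_spec <- 1L
  repeat {
    t_next <- if (next_spec <= length(sched)) {
      it$depth[sched[next_spec]]
    } else {
      T_end
    }
    # Poisson events on carrier lineages within [t_now, t_next)
    while (total_rate > 0 && sum(carrier) > 0) {
      dt <- stats::rexp(1L, sum(carrier) * total_rate)
      if (t_now + dt >= t_next) break
      t_now <- t_now + dt
      carr <- which(carrier)
      donor <- if (length(carr) == 1L) carr else sample(carr, 1L)
      if (stats::runif(1L) < hot_rate / total_rate) {
        others <- setdiff(which(alive), donor)
        if (length(others) == 0L) next
        recip <- if (length(others) == 1L) others else sample(others, 1L)
        carrier[recip] <- TRUE
        ev_time <- c(ev_time, t_now)
        ev_type <- c(ev_type, "transfer")
        ev_donor <- c(ev_donor, donor)
        ev_recip <- c(ev_recip, recip)
      } else {
        carrier[donor] <- FALSE
        ev_time <- c(ev_time, t_now)
        ev_type <- c(ev_type, "loss")
        ev_donor <- c(ev_donor, donor)
        ev_recip <- c(ev_recip, NA_integer_)
      }
    }
    if (next_spec > length(sched)) break
    v <- sched[next_spec]
    t_now <- it$depth[v]
    for (ch in it$children[[v]]) {
      alive[ch] <- TRUE
      carrier[ch] <- carrier[v]
    }
    alive[v] <- FALSE
    carrier[v] <- FALSE
    next_spec <- next_spec + 1L
  }
  events <- data.frame(time = ev_time, type = ev_type, donor = ev_donor,
                       recipient = ev_recip, stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  rep_res <- .replay_genealogy(it, events)
  snames <- .node_names(it)
  events$donor_label <- snames[events$donor]
  events$recipient_label <- ifelse(is.na(events$recipient), NA_character_,
                                   snames[events$recipient])
  structure(list(
    species_tree = as_phylo(tree),
    events = events,
    presence = rep_res$presence,
    operon_tree = rep_res$operon,
    carrier_intervals = rep_res$carrier_intervals,
    n_transfers = sum(events$type == "transfer"),
    n_losses = sum(events$type == "loss")
  ), class = "operon_history")
}

#' @export
print.operon_history <- function(x, ...) {
  cat("operon history on ", length(x$presence), " species: ",
      x$n_transfers, " transfer(s), ", x$n_losses, " loss(es), ",
      sum(x$presence), " carrier tip(s)\n", sep = "")
  invisible(x)
}

#' Species-tree node id of a clade
#'
#' Returns the internal node index (as used in simulator event tables) of
#' the most recent common ancestor of `tips`, or of the tip itself for a
#' single label.  The indexing is deterministic for a given tree.
#'
#' @param tree a `phylo` tree.
#' @param tips one or more tip labels.
#' @return integer node id.
#' @export
node_id <- function(tree, tips) {
  it <- as_itree(tree)
  tips <- sort(unique(as.character(tips)))
  miss <- setdiff(tips, it$label[it$is_tip])
  if (length(miss) > 0L) {
    stop("tip label(s) absent from tree: ", paste(miss, collapse = ", "))
  }
  if (length(tips) == 1L) return(which(it$label == tips))
  cl <- itree_clades(it)
  best <- it$root
  for (v in it$postorder) {
    if (all(tips %in% cl[[v]]) && length(cl[[v]]) < length(cl[[best]])) {
      best <- v
    }
  }
  best
}

#' Simulate gene trees evolving inside the operon
#'
#' Each gene inherits the operon genealogy (vertical descent plus all
#' whole-operon transfers and losses) and is additionally hit by
#' gene-level horizontal transfers at `hgt_rate` per carrier lineage per
#' unit time; each such event is a further timed SPR between two carrier
#' lineages.  A `planted` table injects deterministic transfers (e.g. one
#' forced event in one gene) for ground-truth experiments.
#'
#' @param history an `operon_history`.
#' @param hgt_rate per-gene transfer rate (>= 0).
#' @param n_genes number of genes (>= 1).
#' @param seed optional integer seed.
#' @param planted optional data frame (gene, time, donor, recipient) of
#'   forced transfers; donor/recipient are species node ids (see
#'   [node_id()]) that must be carrier lineages at that time.
#' @return a list with `trees` (named list of `phylo`, `g01..`), and
#'   `events` (named list of per-gene transfer tables).
#' @export
simulate_gene_trees <- function(history, hgt_rate, n_genes, seed = NULL,
                                planted = NULL) {
  stopifnot(inherits(history, "operon_history"))
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (hgt_rate < 0) stop("hgt_rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  it <- as_itree(history$species_tree)
  iv <- history$carrier_intervals
  base_events <- history$events[, c("time", "type", "donor", "recipient")]
  gnames <- sprintf("g%02d", seq_len(n_genes))
  trees <- vector("list", n_genes)
  ev_out <- vector("list", n_genes)
  names(trees) <- gnames
  names(ev_out) <- gnames
  for (g in seq_len(n_genes)) {
    ge <- data.frame(time = numeric(0), donor = integer(0),
                     recipient = integer(0))
    if (hgt_rate > 0 && nrow(iv) > 0L) {
      for (i in seq_len(nrow(iv))) {
        len <- iv$to[i] - iv$from[i]
        k <- stats::rpois(1L, hgt_rate * len)
        if (k == 0L) next
        for (tt in sort(stats::runif(k, iv$from[i], iv$to[i]))) {
          others <- setdiff(.carriers_at(iv, tt), iv$edge[i])
          if (length(others) == 0L) next
          r <- if (length(others) == 1L) others else sample(others, 1L)
          ge <- rbind(ge, data.frame(time = tt, donor = iv$edge[i],
                                     recipient = r))
        }
      }
    }
    if (!is.null(planted)) {
      pg <- planted[planted$gene == g, , drop = FALSE]
      for (i in seq_len(nrow(pg))) {
        carr <- .carriers_at(iv, pg$time[i])
        if (!(pg$donor[i] %in% carr) || !(pg$recipient[i] %in% carr)) {
          stop("planted transfer for gene ", g, " at time ",
               signif(pg$time[i], 4),
               ": donor and recipient must both be carrier lineages")
        }
        ge <- rbind(ge, data.frame(time = pg$time[i], donor = pg$donor[i],
                                   recipient = pg$recipient[i]))
      }
    }
    merged <- rbind(
      base_events,
      if (nrow(ge) > 0L) {
        data.frame(time = ge$time, type = "transfer", donor = ge$donor,
                   recipient = ge$recipient)
      } else {
        NULL
      }
    )
    merged <- merged[order(merged$time), , drop = FALSE]
    rep_res <- .replay_genealogy(it, merged)
    if (!identical(rep_res$presence, history$presence)) {
      stop("internal error: gene presence diverged from operon presence")
    }
    trees[[g]] <- rep_res$operon
    ev_out[[g]] <- ge[order(ge$time), , drop = FALSE]
  }
  list(trees = trees, events = ev_out)
}

#' Plant non-interacting, topology-changing operon transfers
#'
#' Builds an operon history containing exactly `n_hot` horizontal operon
#' transfers chosen so that (i) donor and recipient edges are incomparable
#' and not siblings (each SPR changes the unrooted topology) and (ii) the
#' donor/recipient clades of different events are pairwise disjoint with
#' distinct parent nodes (events do not interact), with no losses.  Used
#' for parameter-recovery experiments where the inferred HOT count should
#' equal the planted count.
#'
#' @param tree ultrametric binary `phylo` species tree.
#' @param n_hot number of transfers to plant.
#' @param seed optional integer seed.
#' @return an `operon_history` (presence everywhere, `n_losses = 0`).
#' @export
simulate_planted_hots <- function(tree, n_hot, seed = NULL) {
  if (n_hot < 1) stop("n_hot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  it <- as_itree(tree)
  .require_binary_rooted(it, "species")
  T_end <- .check_ultrametric(it)
  cl <- itree_clades(it)
  anc <- itree_anc(it)
  span_from <- ifelse(seq_len(it$n) == it$root, NA_real_,
                      it$depth[pmax(it$parent, 1L)])
  span_to <- ifelse(it$is_tip, T_end, it$depth)
  nodes <- setdiff(seq_len(it$n), it$root)
  cand <- list()
  for (d in nodes) {
    for (r in nodes) {
      if (d == r) next
      if (anc[d, r] || anc[r, d]) next
      if (it$parent[d] == it$parent[r]) next      # siblings: no-op SPR
      lo <- max(span_from[d], span_from[r])
      hi <- min(span_to[d], span_to[r])
      if (hi <= lo) next
      cand[[length(cand) + 1L]] <- list(d = d, r = r, lo = lo, hi = hi)
    }
  }
  sizes <- vapply(cand, function(cc) {
    length(cl[[cc$d]]) + length(cl[[cc$r]])
  }, 1L)
  chosen <- list()
  for (attempt in seq_len(200L)) {
    # shuffle, then prefer small clades so many events pack together
    ord <- sample.int(length(cand))
    ord <- ord[order(sizes[ord])]
    used_tips <- character(0)
    used_parents <- integer(0)
    chosen <- list()
    for (cc in cand[ord]) {
      if (length(chosen) >= n_hot) break
      tips_cc <- c(cl[[cc$d]], cl[[cc$r]])
      pars <- c(it$parent[cc$d], it$parent[cc$r])
      if (length(intersect(tips_cc, used_tips)) > 0L) next
      if (length(intersect(pars, used_parents)) > 0L) next
      chosen[[length(chosen) + 1L]] <- cc
      used_tips <- c(used_tips, tips_cc)
      used_parents <- c(used_parents, pars)
    }
    if (length(chosen) >= n_hot) break
  }
  if (length(chosen) < n_hot) {
    stop("could only place ", length(chosen), " of ", n_hot,
         " non-interacting transfers; use a larger tree or fewer events")
  }
  events <- do.call(rbind, lapply(chosen, function(cc) {
    data.frame(time = stats::runif(1L, cc$lo, cc$hi), type = "transfer",
               donor = cc$d, recipient = cc$r, stringsAsFactors = FALSE)
  }))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  rep_res <- .replay_genealogy(it, events)
  snames <- .node_names(it)
  events$donor_label <- snames[events$donor]
  events$recipient_label <- snames[events$recipient]
  structure(list(
    species_tree = as_phylo(tree),
    events = events,
    presence = rep_res$presence,
    operon_tree = rep_res$operon,
    carrier_intervals = rep_res$carrier_intervals,
    n_transfers = nrow(events),
    n_losses = 0L
  ), class = "operon_history")
}

#' Attach bootstrap supports to a simulated tree
#'
#' Every internal non-root edge receives the true-edge support value;
#' optionally `n_low` randomly chosen internal edges are degraded to
#' `low_support` instead (e.g. to create weakly supported regions).
#'
#' @param tree binary `phylo` tree.
#' @param support support for true edges (default 100).
#' @param n_low number of edges degraded to `low_support` (default 0).
#' @param low_support degraded value (default 40).
#' @param seed optional integer seed for the degraded-edge choice.
#' @return a `phylo` tree with supports in `node.label`.
#' @export
assign_supports <- function(tree, support = 100, n_low = 0,
                            low_support = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- as_tnode(tree)
  idx <- 0L
  count_internal <- function(n, is_root) {
    if (t_is_leaf(n)) return(0L)
    sum(vapply(n$children, count_internal, 0L, is_root = FALSE)) +
      (if (is_root) 0L else 1L)
  }
  n_int <- count_internal(nd, TRUE)
  low_set <- if (n_low > 0L && n_int > 0L) {
    sample.int(n_int, min(n_low, n_int))
  } else {
    integer(0)
  }
  assign_rec <- function(n, is_root) {
    if (t_is_leaf(n)) return(n)
    n$children <- lapply(n$children, assign_rec, is_root = FALSE)
    if (!is_root) {
      idx <<- idx + 1L
      n$support <- if (idx %in% low_set) low_support else support
    } else {
      n$support <- NA_real_
    }
    n
  }
  tnode_to_phylo(assign_rec(nd, TRUE))
}

#' Perturb a tree by random nearest-neighbour interchanges
#'
#' Applies `n_nni` NNIs at distinct internal edges; each rearranged edge is
#' stamped with `low_support` (all other supports unchanged), creating the
#' weakly-supported wrong edges that the fixing stage is designed to
#' repair.  A single NNI moves the unrooted Robinson-Foulds distance to the
#' input by exactly 2 (one bipartition swapped for another).
#'
#' @param tree binary `phylo` tree with >= 4 leaves.
#' @param n_nni number of interchanges (>= 0; at most the number of
#'   NNI-eligible internal edges).
#' @param low_support support stamped on rearranged edges (default 40).
#' @param seed optional integer seed.
#' @return a `phylo` tree.
#' @export
perturb_topology <- function(tree, n_nni, low_support = 40, seed = NULL) {
  if (n_nni < 0) stop("n_nni must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nd <- as_tnode(tree)
  if (!t_is_binary(nd)) stop("tree must be binary")
  if (t_n_leaves(nd) < 4L) stop("tree must have >= 4 leaves")
  if (n_nni == 0L) return(as_phylo(tree))
  # eligible edges: internal non-root nodes with an internal child position
  count_eligible <- function(n, is_root) {
    if (t_is_leaf(n)) return(0L)
    here <- if (!is_root) 1L else 0L
    here + sum(vapply(n$children, count_eligible, 0L, is_root = FALSE))
  }
  n_edges <- count_eligible(nd, TRUE)
  if (n_nni > n_edges) {
    stop("n_nni (", n_nni, ") exceeds the number of internal edges (",
         n_edges, ")")
  }
  targets <- sort(sample.int(n_edges, n_nni))
  swaps <- sample(1:2, n_nni, replace = TRUE)
  for (j in seq_len(n_nni)) {
    idx <- 0L
    apply_rec <- function(n, is_root) {
      if (t_is_leaf(n)) return(n)
      for (i in seq_along(n$children)) {
        v <- n$children[[i]]
        if (!t_is_leaf(v)) {
          idx <<- idx + 1L
          if (idx == targets[j]) {
            w_i <- if (i == 1L) 2L else 1L
            w <- n$children[[w_i]]
            x_i <- swaps[j]
            x <- v$children[[x_i]]
            v$children[[x_i]] <- w
            v$support <- low_support
            n$children[[w_i]] <- x
            n$children[[i]] <- v
            return(n)
          }
          n$children[[i]] <- apply_rec(v, FALSE)
        }
      }
      n
    }
    nd <- apply_rec(nd, TRUE)
  }
  tnode_to_phylo(nd)
}

#' Simulate a complete study-style data bundle
#'
#' Generates a species tree, an operon history, per-gene trees, and
#' supports in one call under a single seed.  The defaults emulate the
#' scale of the motivating study design: 44 species, transfer and loss
#' rates tuned to roughly 7 operon transfers and 8 losses in expectation,
#' 33 genes with a low per-gene transfer rate, and fully supported true
#' edges.  A history leaving fewer than `min_carriers` carrier tips is
#' redrawn deterministically (seed offset by 1000 each attempt).
#'
#' @param n_species,birth_rate species-tree parameters.
#' @param hot_rate,loss_rate operon event rates.
#' @param n_genes,hgt_rate gene-tree parameters.
#' @param support,n_low,low_support support model (see [assign_supports()]).
#' @param min_carriers minimal number of surviving carrier tips
#'   (default 4).
#' @param seed integer seed determining every output.
#' @return a list: `species_tree`, `history`, `operon_tree` (with
#'   supports), `gene_trees` (named list, with supports), `presence`,
#'   `truth` (event tables).
#' @export
simulate_study_bundle <- function(n_species = 44, birth_rate = 1,
                                  hot_rate = 0.16, loss_rate = 0.19,
                                  n_genes = 33, hgt_rate = 0.03,
                                  support = 100, n_low = 0,
                                  low_support = 40, min_carriers = 4,
                                  seed = 1) {
  sp <- simulate_species_tree(n_species, birth_rate, seed = seed)
  hist <- NULL
  for (try in 0:49) {
    cand <- simulate_operon_history(sp, hot_rate, loss_rate,
                                    seed = seed + 1000L * try + 1L)
    if (sum(cand$presence) >= min_carriers) {
      hist <- cand
      break
    }
  }
  if (is.null(hist)) {
    stop("could not obtain a history with >= ", min_carriers,
         " carriers; lower loss_rate")
  }
  genes <- simulate_gene_trees(hist, hgt_rate, n_genes, seed = seed + 2L)
  sup_seed <- seed + 3L
  operon_sup <- assign_supports(hist$operon_tree, support, n_low,
                                low_support, seed = sup_seed)
  gene_sup <- lapply(seq_along(genes$trees), function(i) {
    assign_supports(genes$trees[[i]], support, n_low, low_support,
                    seed = sup_seed + i)
  })
  names(gene_sup) <- names(genes$trees)
  list(
    species_tree = sp,
    history = hist,
    operon_tree = operon_sup,
    gene_trees = gene_sup,
    presence = hist$presence,
    truth = list(operon_events = hist$events, gene_events = genes$events)
  )
}
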