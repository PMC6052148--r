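#' Find supported topological conflicts against a reference tree
#'
#' Scans an associate (gene or operon) tree for bipartitions that are
#' incompatible with at least one reference bipartition and whose bootstrap
#' support strictly exceeds `theta_assoc` — the operational definition of a
#' putative horizontal-transfer signal.  The unit of "one conflict" is one
#' supported associate bipartition (not one displaced taxon).  Edges without
#' a support value are treated as unsupported (support 0) for the threshold,
#' so they never produce a record.  Trees on unequal taxon sets are pruned
#' to the shared taxa first (reported via a message).
#'
#' @param assoc associate `phylo` tree with supports in `node.label`.
#' @param ref reference `phylo` tree.
#' @param theta_assoc detection threshold in percent (default 70; the
#'   conflict must be supported *strictly above* it).
#' @return a data frame of class `hot_conflicts`, one row per conflict:
#'   `split` (canonical key of the associate bipartition), `support`,
#'   `n_ref_incompatible`, `max_ref_support` (missing reference supports
#'   count as 0), `class` (initially `"unclassified"`), in canonical order.
#'   Attributes `taxa` and `theta_assoc` record the scan context.
#' @seealso [classify_conflicts()], [scan_gene_set()]
#' @export
find_supported_conflicts <- function(assoc, ref, theta_assoc = 70) {
  pr <- prune_to_common(assoc, ref)
  ab <- bipartition_set(pr$t1)
  rb <- bipartition_set(pr$t2)
  taxa <- attr(ab, "taxa")
  asup <- ifelse(is.na(ab$support), 0, ab$support)
  rsup <- ifelse(is.na(rb$support), 0, rb$support)
  rows <- list()
  rbips <- lapply(rb$split, key_to_bip, taxa = taxa)
  for (i in seq_len(nrow(ab))) {
    if (asup[i] <= theta_assoc) next
    b <- key_to_bip(ab$split[i], taxa)
    inc <- which(!vapply(rbips, are_compatible, TRUE, b1 = b))
    if (length(inc) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      split = ab$split[i],
      support = ab$support[i],
      n_ref_incompatible = length(inc),
      max_ref_support = max(rsup[inc]),
      class = "unclassified",
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(split = character(0), support = numeric(0),
               n_ref_incompatible = integer(0), max_ref_support = numeric(0),
               class = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$split, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  attr(out, "theta_assoc") <- theta_assoc
  class(out) <- c("hot_conflicts", "data.frame")
  out
}

#' Triage supported conflicts into fixable / reference-uncertain / authentic
#'
#' Applies the three-way triage: (1) a conflict whose bipartition no longer
#' appears among the supported conflicts of the *fixed* associate tree is
#' `"fixable"` — a tree-reconstruction error that the error-aware fixing
#' step resolves; (2) otherwise, if the strongest reference bipartition it
#' contradicts has support at most `theta_ref`, it is
#' `"reference_uncertain"` — the reference itself is too weak there to call
#' a transfer; (3) what remains is `"authentic_hgt"`.  The boundary is
#' inclusive for reference uncertainty (support exactly `theta_ref` counts
#' as weak).
#'
#' @param records a `hot_conflicts` data frame from
#'   [find_supported_conflicts()].
#' @param ref the same reference tree used at detection.
#' @param fixed_assoc the associate tree after [fix_tree()] against `ref`.
#' @param theta_ref reference weakness threshold in percent (default 70).
#' @return `records` with the `class` column filled in.
#' @export
classify_conflicts <- function(records, ref, fixed_assoc, theta_ref = 70) {
  stopifnot(inherits(records, "hot_conflicts"))
  taxa <- attr(records, "taxa")
  ftips <- sort(as_phylo(fixed_assoc)$tip.label)
  if (!identical(sort(taxa), intersect(sort(taxa), ftips)) ||
      !setequal(taxa, ftips)) {
    stop("records were not detected on the same associate taxon set as ",
         "fixed_assoc")
  }
  if (nrow(records) == 0L) return(records)
  fixed_conf <- suppressMessages(
    find_supported_conflicts(fixed_assoc, ref,
                             theta_assoc = attr(records, "theta_assoc"))
  )
  records$class <- ifelse(
    !(records$split %in% fixed_conf$split), "fixable",
    ifelse(records$max_ref_support <= theta_ref, "reference_uncertain",
           "authentic_hgt")
  )
  records
}

#' Scan a set of gene trees for supported conflicts and triage them
#'
#' Runs detection, fixing, and triage for every gene tree against the same
#' reference, and tabulates per-gene and total counts of each class.  Genes
#' with at least one authentic conflict are flagged for exclusion from
#' concatenation-based analyses.
#'
#' @param gene_trees named list of `phylo` gene trees.
#' @param ref reference `phylo` tree (binary).
#' @param theta_assoc conflict detection threshold (strict >; default 70).
#' @param theta_ref reference weakness threshold (inclusive <=; default 70).
#' @param fix_threshold support threshold handed to [fix_tree()]
#'   (default 70).
#' @param costs [dtl_costs()] used by the fixing step.
#' @return a list with `per_gene` (data frame of per-class counts),
#'   `totals` (named vector: conflicts, fixable, reference_uncertain,
#'   authentic_hgt), `conflicts` (all records with a `gene` column), and
#'   `flagged_genes` (genes with >= 1 authentic conflict, sorted).
#' @export
scan_gene_set <- function(gene_trees, ref, theta_assoc = 70, theta_ref = 70,
                          fix_threshold = 70, costs = dtl_costs()) {
  if (!is.list(gene_trees) || length(gene_trees) == 0L) {
    stop("gene_trees must be a nonempty named list of trees")
  }
  if (is.null(names(gene_trees)) || any(!nzchar(names(gene_trees)))) {
    names(gene_trees) <- sprintf("g%02d", seq_along(gene_trees))
  }
  per <- list()
  conf <- list()
  for (g in names(gene_trees)) {
    pr <- suppressMessages(prune_to_common(gene_trees[[g]], ref))
    rec <- suppressMessages(
      find_supported_conflicts(pr$t1, pr$t2, theta_assoc)
    )
    if (nrow(rec) > 0L) {
      fixed <- fix_tree(pr$t1, pr$t2, support_threshold = fix_threshold,
                        costs = costs)$tree
      rec <- classify_conflicts(rec, pr$t2, fixed, theta_ref)
    }
    per[[g]] <- data.frame(
      gene = g,
      conflicts = nrow(rec),
      fixable = sum(rec$class == "fixable"),
      reference_uncertain = sum(rec$class == "reference_uncertain"),
      authentic_hgt = sum(rec$class == "authentic_hgt"),
      stringsAsFactors = FALSE
    )
    if (nrow(rec) > 0L) {
      conf[[g]] <- cbind(gene = g, as.data.frame(rec),
                         stringsAsFactors = FALSE)
    }
  }
  per_gene <- do.call(rbind, per)
  rownames(per_gene) <- NULL
  conflicts <- if (length(conf) > 0L) {
    out <- do.call(rbind, conf)
    rownames(out) <- NULL
    out
  } else {
    data.frame(gene = character(0), split = character(0),
               support = numeric(0), n_ref_incompatible = integer(0),
               max_ref_support = numeric(0), class = character(0),
               stringsAsFactors = FALSE)
  }
  totals <- c(
    conflicts = sum(per_gene$conflicts),
    fixable = sum(per_gene$fixable),
    reference_uncertain = sum(per_gene$reference_uncertain),
    authentic_hgt = sum(per_gene$authentic_hgt)
  )
  list(
    per_gene = per_gene,
    totals = totals,
    conflicts = conflicts,
    flagged_genes = sort(per_gene$gene[per_gene$authentic_hgt > 0L])
  )
}
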