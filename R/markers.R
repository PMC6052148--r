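#' Select operon marker genes by strict exclusion criteria
#'
#' A gene qualifies as a phylogenetic marker for the operon only if it is
#' (i) specific to the operon (no close paralogs or copies elsewhere in the
#' genome), (ii) universally present in the same form across the strains
#' (not replaced by an alternative gene in part of them), and (iii) long
#' enough after alignment-column filtering to carry signal
#' (`filtered_length >= min_length`; the boundary is inclusive — exclusion
#' is strictly "shorter than").  Every excluded gene is tagged with the
#' first criterion it fails, in that order.
#'
#' @param records data frame with columns `gene`, `pgc_specific` (logical),
#'   `universal` (logical), `filtered_length` (non-negative integer).
#' @param min_length minimal post-filter length in residues (default 100).
#' @return a list with `selected` (sorted character vector) and `excluded`
#'   (data frame: gene, reason in `"not_pgc_specific"`, `"not_universal"`,
#'   `"short"`).
#' @examples
#' sel <- select_markers(pgc_gene_catalog())
#' length(sel$selected)   # 33
#' @export
select_markers <- function(records, min_length = 100) {
  need <- c("gene", "pgc_specific", "universal", "filtered_length")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("records must be nonempty")
  dup <- unique(records$gene[duplicated(records$gene)])
  if (length(dup) > 0L) {
    stop("duplicate gene name(s): ", paste(dup, collapse = ", "))
  }
  if (any(records$filtered_length < 0)) {
    stop("filtered_length must be non-negative")
  }
  reason <- ifelse(!records$pgc_specific, "not_pgc_specific",
                   ifelse(!records$universal, "not_universal",
                          ifelse(records$filtered_length < min_length,
                                 "short", NA_character_)))
  keep <- is.na(reason)
  excluded <- data.frame(gene = records$gene[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  excluded <- excluded[order(excluded$gene, method = "radix"), , drop = FALSE]
  rownames(excluded) <- NULL
  list(selected = sort(records$gene[keep]), excluded = excluded)
}

#' Catalog of photosynthesis gene cluster genes with selection annotations
#'
#' The 50 genes of the *Dinoroseobacter shibae* DFL-12 reference PGC (locus
#' tags Dshi_3498..Dshi_3547, in cluster order), annotated with the three
#' marker-selection criteria: PGC specificity, universality (*pufC* is
#' alternated with *pufX* in part of the strains), and whether the aligned
#' gene retains at least 100 amino-acid positions after gap/variability
#' column filtering.  Applying [select_markers()] reproduces the 33-marker
#' set used for the concatenated operon phylogeny, with 17 genes excluded.
#'
#' The `filtered_length` column holds category-faithful surrogate values
#' (150 for genes at or above the 100-residue cutoff, 50 for genes below
#' it): the published record states only on which side of the cutoff each
#' gene falls, not its exact post-filter length, and nothing downstream
#' depends on more than the category.
#'
#' @return a data frame with columns `order`, `gene`, `locus_tag`,
#'   `pgc_specific`, `universal`, `filtered_length`, `note`.
#' @export
pgc_gene_catalog <- function() {
  path <- system.file("extdata", "pgc_gene_catalog.tsv", package = "hotrecon",
                      mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$pgc_specific <- as.logical(out$pgc_specific)
  out$universal <- as.logical(out$universal)
  out
}

#' Remove gappy (and optionally hypervariable) alignment columns
#'
#' Drops every column whose gap fraction strictly exceeds
#' `max_gap_fraction` (a column at exactly the threshold is kept).  An
#' optional conservation filter additionally drops columns whose modal
#' non-gap residue frequency falls below `min_conservation`; it is a
#' deliberately coarse approximation of block-based variability filtering
#' and is off by default.  Column order is preserved; kept indices are
#' reported 0-based.
#'
#' @param alignment equal-length sequences: a named character vector, a
#'   character matrix (rows = sequences), or any object `as.character()`
#'   turns into one (e.g. a Biostrings `AAStringSet`).
#' @param max_gap_fraction maximal tolerated gap fraction (default 0.5).
#' @param min_conservation minimal modal-residue frequency among non-gap
#'   characters, in (0, 1\]; `NULL` (default) disables the filter.
#' @return a list with `alignment` (named character vector of filtered
#'   sequences) and `kept` (0-based integer indices of retained columns).
#' @export
filter_alignment_columns <- function(alignment, max_gap_fraction = 0.5,
                                     min_conservation = NULL) {
  if (is.matrix(alignment)) {
    mat <- alignment
  } else {
    seqs <- as.character(alignment)
    if (is.null(names(seqs)) && !is.null(names(alignment))) {
      names(seqs) <- names(alignment)
    }
    if (length(unique(nchar(seqs))) > 1L) {
      stop("alignment is ragged: sequences differ in length")
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) == 0L) {
    return(list(alignment = stats::setNames(rep("", nrow(mat)),
                                            rownames(mat)),
                kept = integer(0)))
  }
  gap <- mat == "-" | mat == "."
  gap_frac <- colMeans(gap)
  keep <- gap_frac <= max_gap_fraction
  if (!is.null(min_conservation)) {
    cons <- vapply(seq_len(ncol(mat)), function(j) {
      res <- mat[!gap[, j], j]
      if (length(res) == 0L) return(0)
      max(table(res)) / length(res)
    }, numeric(1L))
    keep <- keep & cons >= min_conservation
  }
  kept <- which(keep)
  out <- apply(mat[, kept, drop = FALSE], 1L, paste, collapse = "")
  if (nrow(mat) > 0L && is.null(names(out))) names(out) <- rownames(mat)
  list(alignment = out, kept = kept - 1L)
}

#' Per-gene transfer counts relative to a reference tree
#'
#' For each gene tree: prune to the taxa shared with the reference, fix the
#' gene tree against the reference ([fix_tree()]), reconcile
#' ([dtl_reconcile()]), and report the transfer count of the optimal
#' scenario.  Running this once against the operon tree and once against
#' the species tree yields the two count vectors the concerted-evolution
#' test compares.
#'
#' @param gene_trees named list of `phylo` trees.
#' @param reference binary `phylo` reference tree.
#' @param costs [dtl_costs()] scheme (default 2-3-1).
#' @param fix_threshold support threshold for the fixing step (default 70).
#' @return named integer vector of transfer counts.
#' @export
per_gene_transfer_counts <- function(gene_trees, reference,
                                     costs = dtl_costs(),
                                     fix_threshold = 70) {
  if (!is.list(gene_trees) || length(gene_trees) == 0L) {
    stop("gene_trees must be a nonempty list")
  }
  if (is.null(names(gene_trees)) || any(!nzchar(names(gene_trees)))) {
    names(gene_trees) <- sprintf("g%02d", seq_along(gene_trees))
  }
  vapply(gene_trees, function(gt) {
    pr <- suppressMessages(prune_to_common(gt, reference))
    fx <- fix_tree(pr$t1, pr$t2, support_threshold = fix_threshold,
                   costs = costs)
    rec <- dtl_reconcile(fx$tree, pr$t2, costs = costs)
    unname(rec$summary[["transfers"]])
  }, integer(1L))
}

#' Concerted-evolution test on per-gene transfer counts
#'
#' Concerted (joint) evolution of an operon predicts that each gene's
#' transfer count relative to the operon tree is (1) lower than its
#' transfer count relative to the organism tree, and (2) lower than the
#' number of whole-operon transfers (HOTs).  Both predictions are tested
#' one-sidedly: prediction 1 by an exact paired sign test on the
#' differences (species-relative minus operon-relative; zero differences
#' dropped, the standard sign-test convention), prediction 2 by a sign test
#' of the gene counts against the HOT count as a reference value.  A
#' Wilcoxon signed-rank alternative is available.
#'
#' @param counts_vs_operon,counts_vs_species equal-length numeric vectors
#'   of per-gene transfer counts (same gene order).
#' @param n_hot number of inferred whole-operon transfers.
#' @param method `"sign"` (exact, default) or `"wilcoxon"`.
#' @param alpha significance level for the reported prediction verdicts
#'   (default 0.05).
#' @return an object of class `concerted_report`: the two count vectors and
#'   their medians, `n_hot`, `p_vs_species` / `p_vs_hot` (one-sided
#'   p-values), and logical `prediction1` / `prediction2`.
#' @examples
#' concerted_evolution_test(rep(0, 33), rep(2, 33), n_hot = 7)$p_vs_species
#' # 0.5^33
#' @export
concerted_evolution_test <- function(counts_vs_operon, counts_vs_species,
                                     n_hot, method = c("sign", "wilcoxon"),
                                     alpha = 0.05) {
  method <- match.arg(method)
  if (length(counts_vs_operon) != length(counts_vs_species)) {
    stop("count vectors differ in length")
  }
  one_sided <- function(diffs) {
    if (method == "sign") {
      nz <- diffs[diffs != 0]
      if (length(nz) == 0L) return(1)
      stats::pbinom(sum(nz > 0) - 1L, length(nz), 0.5, lower.tail = FALSE)
    } else {
      nz <- diffs[diffs != 0]
      if (length(nz) == 0L) return(1)
      suppressWarnings(
        stats::wilcox.test(nz, alternative = "greater")$p.value
      )
    }
  }
  p1 <- one_sided(counts_vs_species - counts_vs_operon)
  p2 <- one_sided(n_hot - counts_vs_operon)
  structure(list(
    counts_vs_operon = counts_vs_operon,
    counts_vs_species = counts_vs_species,
    median_vs_operon = stats::median(counts_vs_operon),
    median_vs_species = stats::median(counts_vs_species),
    n_hot = n_hot,
    method = method,
    p_vs_species = p1,
    p_vs_hot = p2,
    prediction1 = p1 < alpha,
    prediction2 = p2 < alpha,
    alpha = alpha
  ), class = "concerted_report")
}

#' @export
print.concerted_report <- function(x, ...) {
  cat("concerted-evolution test (", x$method, " test, n = ",
      length(x$counts_vs_operon), " genes)\n", sep = "")
  cat("  median transfers vs operon tree: ", x$median_vs_operon,
      " | vs species tree: ", x$median_vs_species,
      " | HOTs: ", x$n_hot, "\n", sep = "")
  cat(sprintf("  prediction 1 (fewer than vs species tree): p = %.3g -> %s\n",
              x$p_vs_species, if (x$prediction1) "supported" else
                "not supported"))
  cat(sprintf("  prediction 2 (fewer than HOT count):       p = %.3g -> %s\n",
              x$p_vs_hot, if (x$prediction2) "supported" else
                "not supported"))
  invisible(x)
}

#' Do the leaves in a given state form a clade?
#'
#' Checks whether the leaves carrying a diagnostic character state are
#' exactly the leaf set of one node (e.g. whether all strains with a
#' derived gene replacement form a monophyletic group), and reports the
#' support of that node's stem edge.
#'
#' @param tree a `phylo` tree.
#' @param leaf_states named vector (logical, or 0/1) over all leaves; state
#'   1/`TRUE` is the diagnostic state.
#' @return a list: `is_clade` (logical), `support` (stem support; `NA` when
#'   the clade is the whole tree or the stem carries no value), `is_root`
#'   (`TRUE` when the state-1 leaves are all leaves).
#' @export
state_monophyly <- function(tree, leaf_states) {
  it <- as_itree(tree)
  tips <- it$label[it$is_tip]
  if (is.null(names(leaf_states))) stop("leaf_states must be named")
  miss <- setdiff(tips, names(leaf_states))
  if (length(miss) > 0L) {
    stop("leaf_states missing for: ", paste(miss, collapse = ", "))
  }
  ones <- sort(tips[as.logical(leaf_states[tips])])
  if (length(ones) == 0L) stop("no leaf carries state 1")
  if (setequal(ones, tips)) {
    return(list(is_clade = TRUE, support = NA_real_, is_root = TRUE))
  }
  cl <- itree_clades(it)
  for (v in seq_len(it$n)) {
    if (identical(cl[[v]], ones)) {
      return(list(is_clade = TRUE, support = it$support[v], is_root = FALSE))
    }
  }
  list(is_clade = FALSE, support = NA_real_, is_root = FALSE)
}
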