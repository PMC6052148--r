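#' Pipeline configuration
#'
#' Bundles every threshold, cost, and seed of the end-to-end analysis; the
#' configuration is echoed in the report so no default is silent.
#'
#' @param theta_assoc conflict detection threshold (strict >; default 70).
#' @param theta_ref reference weakness threshold (inclusive <=;
#'   default 70).
#' @param fix_threshold support-negotiability threshold for tree fixing
#'   (default 70).
#' @param costs [dtl_costs()] scheme (default 2-3-1).
#' @param alpha significance level of the concerted-evolution test
#'   (default 0.05).
#' @param seed optional integer seed echoed into the report.
#' @return a list of class `hot_config`.
#' @export
hot_config <- function(theta_assoc = 70, theta_ref = 70, fix_threshold = 70,
                       costs = dtl_costs(), alpha = 0.05, seed = NULL) {
  structure(list(theta_assoc = theta_assoc, theta_ref = theta_ref,
                 fix_threshold = fix_threshold, costs = costs,
                 alpha = alpha, seed = seed), class = "hot_config")
}

#' Run the complete horizontal-operon-transfer analysis
#'
#' Executes the study workflow in order: (1) scan every gene tree against
#' the operon reference tree for supported conflicts and triage them
#' (fixable / reference-uncertain / authentic single-gene HGT); (2) fix the
#' operon tree against the species tree wherever its own support allows;
#' (3) reconcile the fixed operon tree with the species tree under DTL
#' parsimony — the transfer count is the minimal number of horizontal
#' operon transfers (HOTs), reported with the loss/duplication counts and
#' the number of co-optimal scenarios; (4) count the losses a pure-loss
#' (Dollo, single origin at the root) null would require for the observed
#' presence/absence pattern, the side-by-side contrast that decides between
#' regressive evolution and horizontal transfer; (5) run the
#' concerted-evolution test on per-gene transfer counts relative to the
#' operon tree versus the species tree.
#'
#' @param species_tree binary `phylo` species tree over all strains.
#' @param operon_tree binary `phylo` operon tree over the carrier strains.
#' @param gene_trees named list of `phylo` gene trees (carrier strains).
#' @param presence named logical vector (or two-column data frame) of
#'   operon presence over all species-tree tips.
#' @param config a [hot_config()].
#' @param out_dir optional directory; when given, every stage input/output
#'   is persisted there (newick trees, TSV tables, and the rendered
#'   report).
#' @return an object of class `hot_report`; see [report_render()].
#' @export
run_hot_analysis <- function(species_tree, operon_tree, gene_trees,
                             presence, config = hot_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "hot_config"))
  stage <- "input validation"
  res <- tryCatch({
    species_tree <- as_phylo(species_tree)
    operon_tree <- as_phylo(operon_tree)
    if (is.data.frame(presence)) {
      presence <- stats::setNames(as.logical(presence[[2L]]),
                                  as.character(presence[[1L]]))
    }

    stage <- "single-gene conflict scan"
    scan <- scan_gene_set(gene_trees, operon_tree,
                          theta_assoc = config$theta_assoc,
                          theta_ref = config$theta_ref,
                          fix_threshold = config$fix_threshold,
                          costs = config$costs)

    stage <- "operon tree fixing"
    pr <- suppressMessages(prune_to_common(operon_tree, species_tree))
    fix <- fix_tree(pr$t1, pr$t2, support_threshold = config$fix_threshold,
                    costs = config$costs)

    stage <- "DTL reconciliation"
    rec <- dtl_reconcile(fix$tree, pr$t2, costs = config$costs)

    stage <- "Dollo loss counting"
    dollo <- dollo_loss_count(species_tree, presence)

    stage <- "concerted-evolution test"
    concerted <- NULL
    if (length(gene_trees) >= 2L) {
      cvo <- per_gene_transfer_counts(gene_trees, operon_tree,
                                      costs = config$costs,
                                      fix_threshold = config$fix_threshold)
      cvs <- per_gene_transfer_counts(gene_trees, species_tree,
                                      costs = config$costs,
                                      fix_threshold = config$fix_threshold)
      concerted <- concerted_evolution_test(
        cvo, cvs, n_hot = unname(rec$summary[["transfers"]]),
        alpha = config$alpha
      )
    }

    structure(list(
      conflict_summary = scan$per_gene,
      conflict_totals = scan$totals,
      conflicts = scan$conflicts,
      flagged_genes = scan$flagged_genes,
      fix = fix,
      reconciliation = rec,
      hot_count = unname(rec$summary[["transfers"]]),
      loss_count = unname(rec$summary[["losses"]]),
      duplication_count = unname(rec$summary[["duplications"]]),
      n_optimal = rec$n_optimal,
      dollo = dollo,
      concerted = concerted,
      config = config
    ), class = "hot_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    .persist_report(res, species_tree, operon_tree, gene_trees, presence,
                    out_dir)
  }
  res
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.persist_report <- function(report, species_tree, operon_tree, gene_trees,
                            presence, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(species_tree), file.path(out_dir, "species.nwk"))
  writeLines(write_newick(operon_tree), file.path(out_dir, "operon.nwk"))
  writeLines(write_newick(report$fix$tree),
             file.path(out_dir, "operon_fixed.nwk"))
  gdir <- file.path(out_dir, "genes")
  dir.create(gdir, showWarnings = FALSE)
  for (g in names(gene_trees)) {
    writeLines(write_newick(gene_trees[[g]]),
               file.path(gdir, paste0(g, ".nwk")))
  }
  .write_tsv(data.frame(taxon = names(presence),
                        present = unname(presence)),
             file.path(out_dir, "presence.tsv"))
  .write_tsv(report$conflict_summary,
             file.path(out_dir, "conflict_summary.tsv"))
  .write_tsv(report$conflicts, file.path(out_dir, "conflicts.tsv"))
  .write_tsv(report$reconciliation$events,
             file.path(out_dir, "reconciliation_events.tsv"))
  .write_tsv(report$dollo$loss_edges, file.path(out_dir, "dollo_losses.tsv"))
  writeLines(report_render(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render an analysis report as deterministic text
#'
#' @param report a `hot_report` from [run_hot_analysis()].
#' @return a character vector of report lines (identical for identical
#'   reports).
#' @export
report_render <- function(report) {
  stopifnot(inherits(report, "hot_report"))
  cfg <- report$config
  lines <- c(
    "== horizontal operon transfer analysis ==",
    "",
    sprintf("configuration: theta_assoc=%g theta_ref=%g fix_threshold=%g",
            cfg$theta_assoc, cfg$theta_ref, cfg$fix_threshold),
    sprintf("  DTL costs: duplication=%g transfer=%g loss=%g; alpha=%g%s",
            cfg$costs$dup, cfg$costs$transfer, cfg$costs$loss, cfg$alpha,
            if (is.null(cfg$seed)) "" else sprintf("; seed=%d",
                                                   as.integer(cfg$seed))),
    "",
    "-- single-gene conflicts --",
    sprintf("total: %d (fixable %d, reference-uncertain %d, authentic %d)",
            report$conflict_totals[["conflicts"]],
            report$conflict_totals[["fixable"]],
            report$conflict_totals[["reference_uncertain"]],
            report$conflict_totals[["authentic_hgt"]]),
    sprintf("flagged genes (authentic HGT): %s",
            if (length(report$flagged_genes) == 0L) "none" else
              paste(report$flagged_genes, collapse = ", ")),
    "",
    "-- operon tree fixing --",
    sprintf("bipartitions removed %d, added %d; DTL cost %g -> %g",
            length(report$fix$removed), length(report$fix$added),
            report$fix$cost_before, report$fix$cost_after),
    "",
    "-- reconciliation (fixed operon tree vs species tree) --",
    sprintf("HOTs (transfers): %d; losses: %d; duplications: %d",
            report$hot_count, report$loss_count, report$duplication_count),
    sprintf("co-optimal scenarios: %s", format(report$n_optimal)),
    "",
    "-- vertical-inheritance null (Dollo, single origin) --",
    sprintf("independent losses required: %d", report$dollo$n_losses),
    sprintf("contrast: %d Dollo losses vs %d HOTs + %d losses under DTL",
            report$dollo$n_losses, report$hot_count, report$loss_count)
  )
  if (!is.null(report$concerted)) {
    cc <- report$concerted
    lines <- c(lines, "",
      "-- concerted evolution --",
      sprintf("median per-gene transfers vs operon tree: %g; vs species tree: %g",
              cc$median_vs_operon, cc$median_vs_species),
      sprintf("prediction 1 (vs species tree): p = %.4g -> %s",
              cc$p_vs_species,
              if (cc$prediction1) "supported" else "not supported"),
      sprintf("prediction 2 (vs %d HOTs): p = %.4g -> %s", cc$n_hot,
              cc$p_vs_hot,
              if (cc$prediction2) "supported" else "not supported"))
  }
  lines
}

#' @export
print.hot_report <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}
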