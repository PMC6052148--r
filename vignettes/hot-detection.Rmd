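---
title: "Detecting horizontal operon transfer by tree reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal operon transfer by tree reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotrecon)
```

## The problem

Bacterial operons that encode a complete, selectable phenotype — the
photosynthesis gene cluster (PGC) of *Rhodobacteraceae* is the motivating
case — are sometimes found scattered across a family's phylogeny: closely
related strains differ in whether they carry the cluster, and the cluster's
own phylogeny need not match the organisms'.  Two evolutionary accounts
compete:

* **Regressive evolution**: the family's ancestor carried the operon and
  extant absence reflects repeated independent loss.
* **Horizontal operon transfer (HOT)**: the operon moved between lineages
  as a unit (e.g. on a plasmid), so presence reflects a mixture of vertical
  descent, transfer, and loss.

`hotrecon` implements the comparative test between these accounts using
only rooted trees with bootstrap supports, a presence/absence table, and a
gene-annotation catalog.  The workflow: select reliable marker genes;
detect and triage supported conflicts between each gene tree and the
operon reference tree (single-gene transfers must be separated from
whole-operon signal); fix the operon tree against the species tree
wherever its own support permits; reconcile the fixed operon tree with the
species tree under duplication–transfer–loss (DTL) parsimony to obtain the
minimal HOT count; and contrast that with the loss count a pure-loss
(Dollo) null requires.

## The DTL parsimony model

`dtl_reconcile()` solves the undated DTL reconciliation problem: given a
rooted binary gene (or operon) tree $G$, a rooted binary species tree $S$,
a leaf mapping $\sigma$, and costs $(\delta, \tau, \lambda)$ for
duplication, transfer, and loss (default $2, 3, 1$, the cost matrix of the
TreeFix-DTL/NOTUNG tool family), find a minimum-cost assignment of each
internal gene node $g$ to a species node $s$ together with an event label:

* **speciation** — $g$'s children separate into the two child subtrees of
  $s$ (cost 0);
* **duplication** — both children remain in the subtree of $s$ (cost
  $\delta$);
* **transfer** — one child stays under $s$, the other maps under a species
  node *incomparable* to $s$ (neither ancestral to the other; cost
  $\tau$);
* **losses** — every species edge a gene lineage crosses without an
  accounted descendant costs $\lambda$.

The dynamic program is the standard three-table recurrence over
$(g, s)$ pairs: $C(g,s)$ (cost with $g$ mapped at $s$), $\mathrm{IN}(g,s)$
(cheapest entry into the subtree of $s$, charging a loss per skipped
edge), and $\mathrm{OUT}(g,s)$ (cheapest arrival at a node incomparable to
$s$, computed in one preorder sweep from subtree minima).  The gene root
maps anywhere without loss charges above it.  Runtime is
$O(|G|\,|S|)$ per table with small constants; a 44-tip pair reconciles in
about 0.1 s.

Three design points deserve emphasis:

* **Co-optimal counting.**  A companion counting program sums, at every
  tie, the number of optimal sub-assignments and multiplies over
  independent children, yielding the exact number of co-optimal
  (mapping, event-label) assignments (`n_optimal`).
  `enumerate_scenarios()` reproduces them one by one by backtracking, so
  `length(enumerate_scenarios(...))` equals `n_optimal` whenever the limit
  allows.  We count distinct (mapping, label) assignments because no finer
  equivalence is canonical for undated reconciliations.
* **Deterministic tie-breaking.**  The reported single scenario prefers
  speciation over duplication over transfer at equal cost, and the
  smallest species-node index among tied placements, so identical inputs
  always yield identical reports.
* **No global transfer timing.**  Undated parsimony does not enforce a
  consistent time ordering across transfers (doing so exactly is
  NP-hard).  A post-hoc heuristic builds the precedence digraph implied by
  donor/recipient ancestry and flags cycles via `time_consistent`; the
  flag warns, it does not change the optimum.

A useful consequence of the loss rule: a gene tree that differs from the
species tree by one topology-changing SPR generically reconciles as one
transfer *plus one loss* (the vacated source position), cost 4 under
2-3-1.  Whole-operon replacement transfers therefore surface as paired
"$k$ HOTs + $k$ losses" patterns before error-aware fixing.

## Dollo loss counting

Under the vertical-inheritance null the operon is gained once at the root
and never regained, so the observed presence pattern must be produced by
losses alone.  The minimum number of losses equals the number of maximal
all-absent clades; `dollo_loss_count()` returns that count and the stem
edges.  This is the quantity contrasted with the reconciliation's
HOT-plus-loss tally in the final report.

## Conflict detection and triage

`find_supported_conflicts()` defines one conflict as one associate-tree
bipartition that is (i) supported strictly above `theta_assoc` (default
70%, following the ">70% bootstrap" convention) and (ii) incompatible
with at least one reference bipartition.  Edges without a support value
never produce a record (they count as support 0 at detection) but are also
never collapsed by the fixing stage (missing evidence is not
contradiction).  `classify_conflicts()` then triages, in order:

1. **fixable** — the conflict is absent from the supported-conflict set of
   the *fixed* associate tree: a reconstruction error the data do not
   defend;
2. **reference_uncertain** — the strongest contradicted reference edge has
   support $\le$ `theta_ref` (the boundary is inclusive: a 70%-supported
   reference edge counts as weak);
3. **authentic_hgt** — everything else.

Because fixing preserves all edges at or above its threshold, a conflict
detected above the same threshold always survives fixing; the fixable
class is populated when detection is run more permissively than fixing
(e.g. scanning at `theta_assoc = 30` while fixing at 70), which is exactly
how weakly supported wrong edges are audited.

## Error-aware tree fixing

The likelihood-based fixers this stage emulates decide which edges are
statistically negotiable from per-site likelihoods of the alignment.
Alignments are not inputs here, so `fix_tree()` uses the only statistical
signal trees carry: bootstrap support.  Edges below `support_threshold`
(default 70) are collapsed (`collapse_low_support()`; contraction adds the
collapsed edge length to the promoted children so tip depths are
preserved), and each polytomy is re-resolved to minimise the DTL cost
against the reference:

* up to 6 children: exhaustively over all $(2k-3)!!\le 945$ rooted
  resolutions, so the chosen resolution is provably cost-minimal;
* above 6: greedy stepwise insertion in canonical order (children sorted
  by smallest leaf label), each step choosing the cost-minimal attachment,
  ties broken by enumeration order.

Polytomies are processed deepest-first; while one polytomy is scored, any
other still-unresolved polytomy is temporarily resolved by a canonical
comb, so joint optimality across several polytomies is heuristic.  A final
safeguard compares the result with the input and returns the input when no
improvement was achieved, which makes `cost_after <= cost_before`
unconditional.  Fixing never re-roots and never touches supported
structure, and it is idempotent: a fixed tree has no sub-threshold edges
left to collapse.

## Marker selection, column filtering, and the concerted test

`select_markers()` applies the three exclusion criteria of the catalog
(operon specificity, universality, $\ge$ 100 retained residues after
column filtering; the length boundary is inclusive).  On the bundled
50-gene PGC catalog this selects 33 markers and excludes 17.  The
catalog's `filtered_length` column stores category-faithful surrogates
(150/50) because exact post-filter lengths are not part of the published
record; only the category matters downstream.

`filter_alignment_columns()` removes columns with strictly more than 50%
gaps (a column at exactly 50% is kept).  The companion "highly variable
positions" rule of block-based filters is multi-parameter and not emulated
bit-exactly; an optional conservation filter (drop columns whose modal
non-gap residue frequency is below `min_conservation`) is provided, off by
default, and documented as approximate.

`concerted_evolution_test()` evaluates the two predictions of joint
operon evolution: each gene's transfer count relative to the operon tree
should be (1) lower than its count relative to the organism tree and (2)
lower than the HOT count.  The primary test is the exact one-sided sign
test (ties dropped; all-$n$ positive differences give $p = 0.5^n$), with a
Wilcoxon signed-rank option; the exact test was chosen as primary because
transfer counts are small discrete numbers with many ties, where the sign
test's assumptions are weakest.

## The simulator and what it does (not) emulate

`simulate_study_bundle()` generates data with the study's structure: a
Yule species tree (`ape::rphylo`, ultrametric), an operon evolving forward
in time with transfers at `hot_rate` and losses at `loss_rate` per carrier
lineage, gene trees inheriting the operon genealogy plus per-gene
transfers at `hgt_rate`, and supports assigned directly to edges.  A
transfer is a timed SPR with replacement: the recipient's copy lineage is
displaced by the donor's.  Recipients are drawn uniformly among
contemporaneous lineages (a distance-biased kernel is a deliberate
non-feature of the defaults).  Losses are lineage-terminal; regain happens
only by transfer, matching the Dollo logic of the null.

Defaults are fixed at the study's scale and were chosen once from the
design, not tuned: 44 species, birth rate 1 (expected tree length
$(n-1)/b = 43$), `hot_rate = 0.16` and `loss_rate = 0.19` so that the
expected numbers of operon transfers and losses are near 7 and 8, 33
genes, `hgt_rate = 0.03` (about one transfer per gene lineage, i.e. a few
percent of gene × strain cells affected), true-edge support 100.  Every
output is a deterministic function of the seed.

What the simulator does **not** model — and hence what passing tests do
not show about real data: sequence evolution and alignment error (supports
are assigned, not estimated; real bootstrap values correlate with branch
length and signal), rate heterogeneity among lineages, gene-tree
estimation error beyond the support model, incomplete taxon sampling of
donors (real transfers often come from unsampled lineages), and any
synteny or plasmid-location information.

## Numerical choices and degenerate inputs

* Supports are integers in $[0,100]$ stored as internal-node labels;
  whole-tree values in $[0,1]$ are rescaled ×100 with a message; values
  outside the range are errors.
* Strict/inclusive boundaries: conflict detection is strict
  (`support > theta_assoc`), collapse is strict (`support < threshold`),
  reference uncertainty is inclusive (`<= theta_ref`), marker length is
  inclusive (`>= min_length`), gap filtering is strict (`> 0.5` removed).
* Rooted trees with two root children induce the same unrooted split
  twice; `bipartition_set()` reports it once with the larger annotated
  support.
* Degenerate inputs error early with named offenders: duplicate leaves,
  unbalanced parentheses (with position), non-binary trees handed to the
  reconciler (pointed to `fix_tree()`), unknown or missing taxa in
  presence tables and leaf maps, disjoint taxon sets.
* Taxon-set mismatches between associate and reference trees are resolved
  by pruning to the common set, reported via a message.
* All set-valued outputs are sorted canonically; reports render
  byte-identically for identical inputs.

## Validation regime and problem sizes

The test suite validates the reconciliation engine against an independent
brute-force oracle that enumerates every mapping of internal gene nodes to
species nodes and minimises/counts event labels per node (they are
separable given a mapping).  Random gene/species pairs use 4–7-leaf
species trees paired with gene trees small enough that the full mapping
enumeration stays within a few hundred thousand rows per pair; 200 such
pairs are checked for both cost and co-optimal count, plus 40 more in the
unit tests.  Dollo counting is checked against exhaustive internal-state
enumeration on 10-leaf trees.  Round-trip serialisation is checked on
1000 random trees of up to 64 leaves.  Parameter recovery runs 100
replicates of 44-tip trees with 7 planted non-interacting transfers; the
package's stated recovery criterion is equality in at least 95% of
replicates and no overcount ever (parsimony can only undercount).
Monte-Carlo rate calibration uses 1000 histories on a 10-tip tree and a
3-standard-error band.  These sizes are the package's validation design;
`scripts/acceptance.R` re-runs condensed versions of each from a single
seed.

## Known limitations

* The DTL model is undated; transfer scenarios may be globally
  time-inconsistent (flagged, not forbidden), and non-binary species trees
  are not supported.
* Fixing substitutes bootstrap support for the original per-site
  statistical test; with uninformative supports it is conservative
  (nothing is negotiable).
* The conflict unit (one supported bipartition) differs from counting
  displaced taxa or transfer events; counts are comparable within this
  package, not across tools.
* With several interacting transfers, parsimony undercounts by design;
  the HOT count is a minimum, not an estimate.
* The greedy regime for >6-way polytomies and the comb placeholder for
  co-occurring polytomies are heuristics; only the $\le$6-way single
  polytomy case is provably optimal.
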