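---
title: "Methods: multiresolution hierarchy-linked barplots"
author: "treestack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiresolution hierarchy-linked barplots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treestack)
```

# The problem

Stacked barplots are the workhorse overview of microbiome community
structure: one bar per sample, one colored segment per taxon. They break
down when the number of taxa exceeds what a qualitative palette can carry —
the usual escape hatches (plot only coarse ranks, or lump rare taxa into
"Other") hide exactly the fine-resolution shifts one often cares about.
treestack implements the computational core of a focus-plus-context answer
to this: the barplot is linked to the taxonomic (or cell-type) hierarchy,
subtrees can be collapsed into merged rectangles, and subtrees at *any*
mix of resolutions can be painted with palette colors and compared across
samples. All interactive gestures are reified as explicit, deterministic
operations on a view-state object, so an analysis is a script, not a
mouse recording.

# Data model

Two inputs are required, mirroring the convention of tree-aware omics
containers:

* an **abundance matrix**, samples in rows and taxa in columns. Values must
  be non-negative but rows need *not* sum to one; any non-compositional
  normalization is accepted, and raw-mode bars then have unequal heights.
* a **hierarchy**: a rooted, not-necessarily-binary labeled tree whose
  leaves are the finest taxonomic units. Leaf labels are the join key to the
  abundance columns, so they must be unique; `validateAbundance()` checks the
  two inputs against each other and reindexes columns into leaf order.

Hierarchies come from Newick text (`parseNewick()`; branch lengths are
parsed and stored but the layout is rank-based, so they are never consumed)
or from a taxonomy rank table (`taxonomyToTree()`), the common less
structured form. Three policies in the taxonomy conversion were genuinely
open and are fixed as follows:

* **Missing cells are skipped.** A row's path is its non-missing cells in
  rank order; no "unclassified" placeholder nodes are created. This keeps
  the tree minimal and collapse semantics unsurprising.
* **Homonyms are distinct nodes.** Taxonomic names repeat across lineages
  (the same class name under two phyla), so internal nodes are keyed by
  their full path (`K1|P1|C1`) while the display label stays the cell value.
  Leaves keep their (unique) label as their id, because that label is the
  join key.
* **Child order is first-appearance order** from the input, never re-sorted,
  which makes every downstream layout reproducible and user-controllable.

# View state

A `ViewState` makes the interactive session explicit: a set of collapsed
nodes, a map of painted nodes to palette colors, and the palette's issue
queue. The semantics follow the interactive tool they model:

* **Collapse** (`collapseNode`) hides a subtree's interior; the barplot
  merges the subtree's leaf columns into a single column
  (`aggregateComposition`), summing abundances so per-sample totals are
  conserved exactly. The visible frontier ("effective leaves") is the set of
  uncollapsed leaves plus maximal collapsed nodes, in tree order.
* **Expand** restores the previous state: paints inside a collapsed subtree
  are *suspended*, not deleted, and return with their original color and
  legend position; collapsed descendants stay collapsed.
* **Paint** (`paintNode`) assigns a palette color to a visible node. Color
  resolution is *nearest painted ancestor wins*: painting a clade colors its
  whole visible subtree except where a descendant carries its own paint,
  which is what lets coarse and fine subtrees be compared simultaneously. A
  collapsed node's single rectangle takes its own paint if any, else its
  nearest painted ancestor, else the neutral gray — a corner case the
  interactive convention leaves open; the rule is the consistent extension
  of the resolution rule.
* **Palette.** The default palette has exactly six colors (a fixed,
  colorblind-safe Okabe-Ito subset; the count is part of the modeled
  interface, the hues are a package choice and overridable). `nextColor()`
  issues indices 0,1,...,5 and then cycles. Color indices are 0-based
  throughout the API, mirroring the number-key selection convention of the
  interactive protocol rather than R's 1-based indexing; this is a
  deliberate, documented exception. If a color survives only inside a
  collapsed subtree it is returned to the palette; whether the original tool
  re-issues it immediately or at cycle end is unstated, so it goes to the
  *front* of the issue queue (re-issued first), which keeps short sessions
  frugal with colors.

Search (`searchLabels`) is a case-insensitive literal substring scan over
*all* labels — internal nodes and leaves — since the modeled interface does
not restrict it; matches come back in pre-order.

# Sample arrangement

Samples can be displayed in input row order (`orderByRows`, for pre-sorted
designs), in the leaf order of a complete-linkage dendrogram
(`orderByClustering`, Euclidean distance by default — the recipe used to
order treatment arms in diet-intervention barplots), or per group
(`orderGrouped`: groups contiguous in display order, clustering applied
independently within each).

Hierarchical clustering is agglomerative with an explicit deterministic
tie-break: among equal-distance merges, the pair whose clusters contain the
smallest original indices merges first, and the cluster holding the smaller
original index becomes the left child. Determinism here is mandatory — the
renderer promises byte-identical output — and exact ties are common in
practice (duplicate samples, integer counts). `stats::hclust` does not
specify its tie policy, so the agglomeration is implemented in the package
(naive O(n^3), entirely adequate for sample counts in the hundreds) and the
test suite cross-checks it against `hclust` partitions on tie-free data.

For very large studies, `selectRepresentatives()` cuts the dendrogram into
`k` clusters and keeps one sample per cluster: the member nearest the
cluster mean (Euclidean, `"centroid"`) or the Bray-Curtis medoid
(`"bc-medoid"`). Bray-Curtis, `sum|x-y| / sum(x+y)`, is computed via
`vegan::vegdist`; it is bounded in [0,1] for non-negative input and is not
a metric (the triangle inequality can fail), which is documented rather
than asserted. Centroids are computed on the input scale — no hidden
relative-abundance normalization — because inputs are allowed to be
non-compositional. The linkage/metric behind the centroid option is not
pinned down by the modeled interface; complete/Euclidean is reused for
consistency with the grouped-ordering recipe. `k` is always user-supplied;
no automatic cluster-count selection is attempted.

# Layout

Layout is pure geometry, independent of the renderer. The canvas
(`canvasSpec`) is abstract units, origin top-left, y downward; the tree
panel sits left of the bar panel. The tree is drawn cladogram-style: the
frontier occupies evenly spaced band centers (the even-spacing "cluster"
convention, which matches the look of the modeled figures better than the
tidy-tree variant), an internal node's y is the mean of its children's, and
x is proportional to topological depth — branch lengths are deliberately
ignored. Only visible nodes are laid out, so collapsing genuinely frees
space. Bars stack top-to-bottom in frontier order, so the top segment of
every bar corresponds to the top leaf of the tree; zero-valued segments are
kept in the layout with zero height (stable sample-by-leaf addressing for
testing) and dropped only at render time. Normalized mode scales each bar
to the panel height; raw mode shares a single global scale set by the
largest arranged sample total.

Hover targeting is a pure query, not an event stream: `hoverMap()` builds a
nearest-site (Voronoi) partition over the laid-out node positions — the
dual of the Delaunay triangulation used by the browser-based original — as
a k-d tree, with exact ties resolved toward the smaller pre-order index.
`queryHover(map, x, y)` returns the owning node for any point.

# Rendering

`renderSvg()` emits a static SVG 1.1 subset (`rect`, `line`, `circle`,
`text`, `g`; no CSS, no script) with stable element ids
(`tree-node-<id>`, `bar-<sample>-<leaf>`, `legend-<i>`), fixed attribute
order, and fixed two-decimal number formatting, so identical inputs give
byte-identical files — snapshot-testable by construction. Collapsed nodes
get a thicker border (stroke multiplier, default 3). Unpainted segments
render in neutral gray `#cccccc` with thin white separators. Sample labels
sit beneath the bars and can be hidden (`hideSampleLabels`, the static
analog of hide-until-hover). The legend lists each painted subtree's root
label in paint insertion order; `labelMode = "on-subtree"` instead places
each label at the painted root's coordinates. Exact fonts and edge joins
are defaults, not contracts.

# Synthetic data

`synthCommunity()` generates the fixture every example and test runs on, so
nothing needs downloading. Defaults describe a small two-arm intervention
study: 20 samples per group; a random 30-leaf taxonomy over four internal
ranks (single kingdom, geometric growth below, every internal node
guaranteed a child); per-leaf log-mean abundances drawn around location 2;
log-normal noise with unit log-sd; 10% zero inflation; counts rounded (not
multinomial, so raw-mode bar totals differ, exercising the
"need-not-sum-to-one" path). A planted effect multiplies the treatment
group's draws on one target subtree by a fold factor *before* rounding, and
the treatment draws on that subtree are control-model draws, so in the
noise-free limit the planted fold is recovered exactly.

A one-time calibration (200 seeds, fold 4, defaults) put the median
empirical fold at 4.08 with every seed showing an excess
(treatment/control ratio > 1); the per-seed spread is dominated by the
random size of the target subtree (2-28 leaves across seeds). The
generator emulates group structure, planted folds, skewed counts and
zeros; it does not emulate compositional closure, sequencing-depth
artifacts, phylogenetic correlation of abundances, or longitudinal
designs — passing tests therefore demonstrate correctness of the
machinery, not robustness to every property of real surveys.

# Numerical and degenerate-input choices

* Aggregation sums leaf columns directly, so per-sample totals are exact
  for integer inputs and conserved to machine precision for reals.
* A normalized bar for an all-zero sample renders as zero-height segments
  rather than an error.
* Clustering with fewer than two samples returns input order with a
  warning; `k = n` representatives is the identity subset; medoid and
  centroid ties go to the smallest sample index.
* Bray-Curtis between two all-zero samples is undefined and raises an
  error naming the pair.
* A single-node layout centers the node vertically; hover queries on one
  site map the whole panel to it.

# Problem sizes used in the test suite

Property-style tests run on randomly generated instances under fixed
seeds: Newick round-trips up to 200 leaves, 500 conservation instances on
trees up to 100 leaves, oracle comparisons for frontier/paint/hover
(1000 query points over ~60 sites) and exhaustive medoid search on
clusters of at most 10 members, and 200 seeded replicates of the
planted-signal recovery. These sizes were chosen to exercise the
asymptotics that matter (ties, deep nesting, zero cells) while keeping the
default check fast on one CPU.

# Known limitations

* No browser interactivity, DOM mutation, or incremental re-layout: the
  view state is the contract, rendering is batch.
* Layout has no branch-length mode and no label-collision avoidance.
* No ordination-based (PCoA/NMDS) sample ordering and no optimal-leaf-order
  dendrogram rearrangement.
* No direct ingestion of phyloseq / TreeSummarizedExperiment objects;
  export to delimited text or Newick first.

# A worked example

```{r example, eval = FALSE}
fx <- synthCommunity(syntheticSpec(seed = 1, fold = 4))
s <- viewState(fx$hierarchy)
s <- collapseNode(s, fx$targetNode)
s <- paintNode(s, fx$targetNode, 0)
arr <- orderGrouped(fx$abundance,
                    setNames(fx$metadata$group, fx$metadata$sample))
doc <- renderView(fx$abundance, s, arr)
saveSvg(doc, "view.svg")
```

The same pipeline is available from a shell via
`inst/scripts/render-view.R`, which adds YAML config layering, view-state
JSON restore, and a JSON sidecar for external renderers.
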