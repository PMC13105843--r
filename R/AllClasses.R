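#' @import methods
NULL

#' Rooted labeled hierarchy over taxa
#'
#' An S4 container for a rooted, not-necessarily-binary tree whose leaves are
#' the finest taxonomic (or cell-type) units. Leaves join to abundance-matrix
#' columns by their label, so leaf labels must be unique across the tree.
#' Nodes are stored in depth-first pre-order; child order is the order of
#' first appearance in the source (Newick text or taxonomy table) and is never
#' re-sorted.
#'
#' @slot nodes data.frame with columns `id` (opaque unique identifier),
#'   `label` (display string), `parent` (id of parent, `NA` for the root),
#'   `rank` (optional rank name, `NA` if unknown) and `length` (branch length,
#'   `NA` if absent; parsed from Newick but unused by the rank-based layout).
#'   Rows are in depth-first pre-order.
#' @slot root id of the root node.
#' @slot leafOrder ids of the leaves in depth-first left-to-right order,
#'   recomputed deterministically from child order.
#' @export
setClass("Hierarchy", representation(
  nodes = "data.frame",
  root = "character",
  leafOrder = "character"
))

setValidity("Hierarchy", function(object) {
  nd <- object@nodes
  need <- c("id", "label", "parent", "rank", "length")
  if (!all(need %in% names(nd))) {
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(nd$id)) {
    return(sprintf("duplicate node ids: %s",
                   paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  }
  roots <- nd$id[is.na(nd$parent)]
  if (length(roots) != 1L) return("exactly one node must have no parent")
  if (!identical(object@root, roots)) return("root slot does not match the parentless node")
  if (!all(nd$parent[!is.na(nd$parent)] %in% nd$id)) return("parent ids must exist")
  # pre-order storage implies every parent precedes its children
  pos <- match(nd$parent, nd$id)
  if (any(pos >= seq_len(nrow(nd)), na.rm = TRUE)) {
    return("nodes must be stored in pre-order (parents before children)")
  }
  lv <- setdiff(nd$id, nd$parent)
  lab <- nd$label[match(lv, nd$id)]
  if (anyDuplicated(lab)) {
    return(sprintf("duplicate leaf labels: %s",
                   paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  if (!setequal(object@leafOrder, lv)) return("leafOrder must contain exactly the leaves")
  TRUE
})

#' Sample-by-taxon abundance matrix
#'
#' Samples in rows, taxa in columns. Values are non-negative but rows need not
#' sum to one: non-compositional normalizations are allowed, giving stacked
#' bars of unequal total height in raw mode. Negative entries are permitted at
#' construction so that [validateAbundance()] can report them; downstream
#' operations require a clean validation.
#'
#' @slot values numeric matrix with sample ids as rownames and taxon ids as
#'   colnames.
#' @export
setClass("AbundanceTable", representation(values = "matrix"))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    return("values must carry sample ids (rownames) and taxon ids (colnames)")
  }
  if (anyDuplicated(rownames(v))) return("duplicate sample ids")
  if (anyDuplicated(colnames(v))) return("duplicate taxon ids")
  if (any(!is.finite(v))) return("values must be finite")
  TRUE
})

#' Cycling color palette
#'
#' An ordered list of hex colors together with an issue queue. Colors are
#' addressed by 0-based index (mirroring number-key selection in the
#' interactive tool). [nextColor()] issues indices in queue order and rotates,
#' so a fresh default palette yields 0,1,2,3,4,5,0,... A color freed because
#' it survives only in suspended paints is moved to the front of the queue and
#' is re-issued first.
#'
#' @slot colors character vector of hex colors (default length six).
#' @slot queue 0-based color indices in issue order; the head is the cursor.
#' @export
setClass("Palette", representation(colors = "character", queue = "integer"))

setValidity("Palette", function(object) {
  n <- length(object@colors)
  if (n < 1L) return("palette must have at least one color")
  if (!setequal(object@queue, seq_len(n) - 1L) || length(object@queue) != n) {
    return("queue must be a permutation of 0..(length-1)")
  }
  TRUE
})

#' Explicit interactive view state
#'
#' Makes the interactive session state programmatic: which subtrees are
#' collapsed, which nodes are painted with which palette color, and the
#' palette's issue queue. Paints lying strictly inside a collapsed subtree are
#' suspended (not deleted) and restored with their original color and
#' insertion position on expand, so collapse/expand round-trips exactly.
#'
#' @slot hierarchy the bound [Hierarchy-class].
#' @slot collapsed ids of collapsed internal nodes.
#' @slot paints data.frame (`node`, `color`, `seq`): active paints in
#'   insertion order (`seq`).
#' @slot suspended data.frame with the same columns: paints hidden by a
#'   collapsed ancestor.
#' @slot palette the [Palette-class].
#' @slot frozen logical; mirrors the freeze-for-export toggle. Informational:
#'   it is serialized with the state but does not gate operations.
#' @slot counter integer; next paint insertion sequence number.
#' @export
setClass("ViewState", representation(
  hierarchy = "Hierarchy",
  collapsed = "character",
  paints = "data.frame",
  suspended = "data.frame",
  palette = "Palette",
  frozen = "logical",
  counter = "integer"
))

setValidity("ViewState", function(object) {
  ids <- object@hierarchy@nodes$id
  bad <- setdiff(c(object@collapsed, object@paints$node, object@suspended$node), ids)
  if (length(bad)) return(sprintf("unknown node ids in state: %s", paste(bad, collapse = ", ")))
  np <- length(object@palette@colors)
  cols <- c(object@paints$color, object@suspended$color)
  if (length(cols) && (any(cols < 0L) || any(cols >= np))) {
    return("paint color indices out of palette range")
  }
  TRUE
})

#' Aggregated composition at the visible frontier
#'
#' The abundance matrix after merging each collapsed subtree's leaf columns
#' into a single column for the collapsed node. Columns are the effective
#' leaves (visible frontier) in tree order; per-sample totals equal the raw
#' per-sample totals exactly.
#'
#' @slot values numeric matrix, samples x effective leaves.
#' @slot colorOf named integer: resolved 0-based palette index per effective
#'   leaf, `NA` where unpainted.
#' @slot labels named character: display label per effective leaf.
#' @export
setClass("EffectiveComposition", representation(
  values = "matrix",
  colorOf = "integer",
  labels = "character"
))

#' Sample arrangement
#'
#' An ordered (possibly representative-subset) sample sequence, with an
#' optional contiguous group partition and an optional cluster-representative
#' mapping.
#'
#' @slot orderedSamples sample ids in display order.
#' @slot groups named character (sample -> group label); length 0 if ungrouped.
#' @slot representatives named character (cluster index -> sample id); length 0
#'   unless representative selection was used.
#' @export
setClass("Arrangement", representation(
  orderedSamples = "character",
  groups = "character",
  representatives = "character"
))

setValidity("Arrangement", function(object) {
  if (anyDuplicated(object@orderedSamples)) return("duplicate samples in arrangement")
  TRUE
})

#' Sample dissimilarity matrix
#'
#' Symmetric, zero-diagonal dissimilarities between samples, tagged with the
#' generating metric. Bray-Curtis entries lie in [0, 1] for non-negative input
#' (and it is not a metric: the triangle inequality can fail).
#'
#' @slot values symmetric numeric matrix with sample ids as dimnames.
#' @slot metric "euclidean" or "bray-curtis".
#' @export
setClass("DissimilarityMatrix", representation(values = "matrix", metric = "character"))

setValidity("DissimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (any(v < 0)) return("dissimilarities must be non-negative")
  TRUE
})

#' Canvas geometry for the two-panel view
#'
#' Abstract drawing units, origin at the top-left with y increasing downward.
#' The tree panel occupies `treeFraction` of the inner width on the left, the
#' bar panel `barFraction` on the right; the remainder is the gutter between
#' them.
#'
#' @slot width,height total canvas size in abstract units.
#' @slot treeFraction,barFraction panel width fractions, each in (0,1), sum <= 1.
#' @slot margin outer margin on all four sides.
#' @slot barGapFraction fraction of each per-sample slot left as gap.
#' @export
setClass("CanvasSpec", representation(
  width = "numeric", height = "numeric",
  treeFraction = "numeric", barFraction = "numeric",
  margin = "numeric", barGapFraction = "numeric"
))

setValidity("CanvasSpec", function(object) {
  if (object@width <= 0 || object@height <= 0) return("dimensions must be positive")
  f <- c(object@treeFraction, object@barFraction)
  if (any(f <= 0) || any(f >= 1) || sum(f) > 1) {
    return("panel fractions must lie in (0,1) and sum to at most 1")
  }
  if (object@margin < 0) return("margin must be non-negative")
  if (object@barGapFraction < 0 || object@barGapFraction >= 1) {
    return("barGapFraction must lie in [0,1)")
  }
  TRUE
})

#' Tree-panel layout
#'
#' Positions for the visible nodes (the frontier plus its ancestors) and the
#' visible parent-child edges. Frontier nodes are evenly spaced band centers,
#' top to bottom in effective-leaf order; an internal node sits at the mean of
#' its children's y and at an x proportional to its topological depth
#' (cladogram style; branch lengths are ignored).
#'
#' @slot nodes data.frame: `id`, `label`, `x`, `y`, `depth`, `collapsed`
#'   (drawn with a thicker border), `frontier`, `preorder`.
#' @slot edges data.frame: `parent`, `child`, `x1`, `y1`, `x2`, `y2`.
#' @slot frontier effective leaf ids, top to bottom.
#' @slot canvas the generating [CanvasSpec-class].
#' @export
setClass("TreeLayout", representation(
  nodes = "data.frame", edges = "data.frame",
  frontier = "character", canvas = "CanvasSpec"
))

#' Bar-panel layout
#'
#' One vertical bar per arranged sample, stacked top-to-bottom in
#' effective-leaf order so the first (top) segment matches the tree's top
#' leaf. Zero-valued segments are kept with zero height for stable
#' (sample x leaf) addressing; the renderer drops them.
#'
#' @slot bars data.frame: `sample`, `x`, `width`.
#' @slot segments data.frame: `sample`, `leaf`, `x`, `y`, `width`, `height`,
#'   `color` (0-based palette index, `NA` unpainted).
#' @slot frontier effective leaf ids (stacking order).
#' @slot normalized logical; if `FALSE`, heights use a global scale set by the
#'   largest sample total, so bar totals may differ.
#' @slot canvas the generating [CanvasSpec-class].
#' @export
setClass("BarLayout", representation(
  bars = "data.frame", segments = "data.frame",
  frontier = "character", normalized = "logical", canvas = "CanvasSpec"
))

#' Nearest-node hover partition
#'
#' A queryable point -> nearest-node map over the tree-panel node positions
#' (the Voronoi partition of the node sites, the dual of the Delaunay
#' triangulation the interactive tool uses for hover targeting). Ties are
#' broken by the smaller pre-order index.
#'
#' @slot ids node ids (site order).
#' @slot sites numeric matrix of (x, y) site coordinates.
#' @slot preorder pre-order index per site (tie-break key).
#' @slot kdtree nested-list k-d tree over the sites.
#' @export
setClass("HoverRegionMap", representation(
  ids = "character", sites = "matrix", preorder = "integer", kdtree = "list"
))

#' Rendering style
#'
#' @slot palette hex colors for paints (default: the six-color palette).
#' @slot neutralColor fill for unpainted segments (default gray `#cccccc`).
#' @slot nodeFontSize,sampleFontSize,legendFontSize font sizes in canvas units.
#' @slot edgeStrokeWidth stroke width of tree edges.
#' @slot collapsedStrokeMultiplier multiplier applied to the node border of
#'   collapsed nodes (they are drawn with a thicker border).
#' @slot labelMode "legend" (separate legend block) or "on-subtree" (legend
#'   text placed at the painted subtree root's coordinates).
#' @slot hideSampleLabels suppress the sample labels beneath the bars.
#' @slot canvas the [CanvasSpec-class] used by the convenience pipeline.
#' @export
setClass("StyleConfig", representation(
  palette = "character", neutralColor = "character",
  nodeFontSize = "numeric", sampleFontSize = "numeric", legendFontSize = "numeric",
  edgeStrokeWidth = "numeric", collapsedStrokeMultiplier = "numeric",
  labelMode = "character", hideSampleLabels = "logical", canvas = "CanvasSpec"
))

setValidity("StyleConfig", function(object) {
  if (!length(object@palette)) return("palette must be non-empty")
  sizes <- c(object@nodeFontSize, object@sampleFontSize, object@legendFontSize,
             object@edgeStrokeWidth, object@collapsedStrokeMultiplier)
  if (any(sizes <= 0)) return("sizes and stroke widths must be positive")
  if (!object@labelMode %in% c("legend", "on-subtree")) {
    return("labelMode must be 'legend' or 'on-subtree'")
  }
  TRUE
})

#' Rendered SVG document
#'
#' Well-formed SVG 1.1 text with stable element ids (`tree-node-<id>`,
#' `bar-<sample>-<leaf>`, `legend-<i>`) and deterministic attribute ordering,
#' so identical inputs produce byte-identical output.
#'
#' @slot content the SVG text (single string).
#' @export
setClass("SvgDocument", representation(content = "character"))

#' Validation report for a hierarchy/abundance pair
#'
#' @slot ok TRUE iff leaves and columns coincide and no value is negative.
#' @slot missingColumns leaf labels absent from the abundance columns.
#' @slot extraColumns abundance columns absent from the leaf labels.
#' @slot negatives data.frame (`sample`, `taxon`, `value`) of negative entries.
#' @slot abundance on success, the abundance table with columns reindexed to
#'   leaf order; otherwise the input unchanged.
#' @export
setClass("ValidationReport", representation(
  ok = "logical", missingColumns = "character", extraColumns = "character",
  negatives = "data.frame", abundance = "AbundanceTable"
))

#' Synthetic community specification
#'
#' Conditions for the synthetic fixture generator: a random taxonomy over
#' `nLeaves` leaves, two sample groups of `nPerGroup`, log-normal base
#' abundances with per-leaf location drawn around `location` and noise
#' `scale`, optional zero inflation, and a planted multiplicative fold change
#' on the leaves under `targetNode` in the treatment group. The treatment
#' draws on the target subtree are the control-model draws scaled by the fold
#' before rounding, so the planted signal is exactly recoverable in the
#' noise-free limit.
#'
#' @slot nPerGroup samples per group.
#' @slot nLeaves number of leaves in the generated taxonomy.
#' @slot ranks rank names, coarse to fine (internal ranks; leaves sit below).
#' @slot targetNode id of the subtree carrying the fold change ("" = first
#'   second-rank node of the generated tree).
#' @slot fold multiplicative group effect (> 0; 1 = null).
#' @slot location mean of the per-leaf log-mean abundances.
#' @slot scale log-normal noise sd (0 switches noise off).
#' @slot zeroProb zero-inflation probability per cell.
#' @slot seed RNG seed (mandatory for reproducibility).
#' @export
setClass("SyntheticSpec", representation(
  nPerGroup = "integer", nLeaves = "integer", ranks = "character",
  targetNode = "character", fold = "numeric", location = "numeric",
  scale = "numeric", zeroProb = "numeric", seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  if (object@fold <= 0) return("fold must be positive")
  if (object@zeroProb < 0 || object@zeroProb > 1) return("zeroProb must lie in [0,1]")
  if (object@scale < 0) return("scale must be non-negative")
  if (object@nPerGroup < 1L || object@nLeaves < 2L) return("need >=1 sample per group and >=2 leaves")
  if (length(object@seed) != 1L || is.na(object@seed)) return("seed is mandatory")
  TRUE
})
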