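#' @include AllClasses.R AllGenerics.R hierarchy.R
NULL

.emptyPaints <- function() {
  data.frame(node = character(0), color = integer(0), seq = integer(0),
             stringsAsFactors = FALSE)
}

#' The default six-color palette
#'
#' Six colorblind-safe hues (Okabe-Ito). The interactive convention this
#' mirrors starts from a six-color palette and cycles once it is exhausted.
#'
#' @return a [Palette-class] with six colors and a fresh issue queue.
#' @export
defaultPalette <- function() {
  newPalette(c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2", "#D55E00"))
}

#' Construct a palette
#'
#' @param colors character vector of hex colors (length >= 1).
#' @return a [Palette-class].
#' @export
newPalette <- function(colors) {
  new("Palette", colors = colors, queue = seq_along(colors) - 1L)
}

#' @describeIn Palette-class the ordered color vector.
#' @export
setMethod("paletteColors", "Palette", function(x) x@colors)

setMethod("show", "Palette", function(object) {
  cat(sprintf("Palette: %d colors, cursor at index %d\n",
              length(object@colors), object@queue[1L]))
})

#' Create a fresh view state bound to a hierarchy
#'
#' Nothing collapsed, nothing painted, full palette, not frozen.
#'
#' @param h a [Hierarchy-class].
#' @param palette a [Palette-class] (default [defaultPalette()]).
#' @return a [ViewState-class].
#' @export
viewState <- function(h, palette = defaultPalette()) {
  new("ViewState", hierarchy = h, collapsed = character(0),
      paints = .emptyPaints(), suspended = .emptyPaints(),
      palette = palette, frozen = FALSE, counter = 1L)
}

#' @describeIn ViewState-class ids of collapsed nodes.
#' @export
setMethod("collapsedNodes", "ViewState", function(x) x@collapsed)

#' @describeIn ViewState-class active paints as a data.frame
#'   (`node`, `color`, `seq`) in insertion order.
#' @export
setMethod("activePaints", "ViewState", function(x) {
  p <- x@paints
  p[order(p$seq), , drop = FALSE]
})

#' @describeIn ViewState-class the bound palette's colors.
#' @export
setMethod("paletteColors", "ViewState", function(x) x@palette@colors)

setMethod("show", "ViewState", function(object) {
  cat(sprintf("ViewState: %d collapsed, %d active paint(s), %d suspended%s\n",
              length(object@collapsed), nrow(object@paints), nrow(object@suspended),
              if (object@frozen) ", frozen" else ""))
})

# is node strictly inside a collapsed subtree?
.hiddenBy <- function(s, id) {
  anc <- .ancestors(s@hierarchy, id)
  anc[anc %in% s@collapsed][1L]  # nearest collapsed ancestor or NA
}

# re-partition paints into active/suspended after the collapsed set changed,
# and adjust the palette queue: colors surviving only in suspended paints are
# returned to the front of the queue (re-issued first); colors that come back
# into active use move to the back.
.repartitionPaints <- function(s) {
  all <- rbind(s@paints, s@suspended)
  if (nrow(all)) {
    hidden <- vapply(all$node, function(n) !is.na(.hiddenBy(s, n)), logical(1))
  } else {
    hidden <- logical(0)
  }
  before <- unique(s@paints$color)
  s@paints <- all[!hidden, , drop = FALSE]
  s@suspended <- all[hidden, , drop = FALSE]
  rownames(s@paints) <- rownames(s@suspended) <- NULL
  after <- unique(s@paints$color)
  freed <- sort(intersect(setdiff(before, after), s@suspended$color))
  revived <- sort(setdiff(after, before))
  q <- s@palette@queue
  if (length(freed)) q <- c(freed, q[!q %in% freed])
  if (length(revived)) q <- c(q[!q %in% revived], revived)
  s@palette@queue <- as.integer(q)
  s
}

#' Collapse a subtree
#'
#' Merges the node's descendant leaves into a single effective leaf.
#' Paints lying strictly inside the collapsed subtree are suspended; if a
#' color survives only in suspended paints it is returned to the palette.
#' Collapsing a leaf, or an already collapsed node, is a no-op.
#'
#' @param s a [ViewState-class].
#' @param id an internal node id.
#' @return the updated [ViewState-class].
#' @export
collapseNode <- function(s, id) {
  stopifnot(is(s, "ViewState"))
  .checkNode(s@hierarchy, id)
  if (isLeaf(s@hierarchy, id) || id %in% s@collapsed) return(s)
  s@collapsed <- c(s@collapsed, id)
  .repartitionPaints(s)
}

#' Expand a collapsed subtree
#'
#' Restores the subtree to its previous state: suspended paints whose node
#' becomes visible are restored with their original color and insertion
#' position; collapsed descendants stay collapsed. Expanding a node that is
#' not collapsed is a no-op (with a message).
#'
#' @param s a [ViewState-class].
#' @param id a collapsed node id.
#' @return the updated [ViewState-class].
#' @export
expandNode <- function(s, id) {
  stopifnot(is(s, "ViewState"))
  .checkNode(s@hierarchy, id)
  if (!id %in% s@collapsed) {
    message(sprintf("expand: node '%s' is not collapsed; nothing to do", id))
    return(s)
  }
  s@collapsed <- setdiff(s@collapsed, id)
  .repartitionPaints(s)
}

#' Visible frontier of effective leaves
#'
#' Depth-first traversal that does not descend into collapsed nodes: the
#' result is the uncollapsed leaves plus the maximal collapsed nodes, in the
#' order induced by leaf order.
#'
#' @param s a [ViewState-class].
#' @return node ids of the effective leaves, top to bottom.
#' @export
effectiveLeaves <- function(s) {
  stopifnot(is(s, "ViewState"))
  h <- s@hierarchy
  kids <- .childMap(h)
  out <- character(0)
  stack <- h@root
  while (length(stack)) {
    id <- stack[[1L]]
    stack <- stack[-1L]
    ch <- kids[[id]]
    if (length(ch) == 0L || id %in% s@collapsed) {
      out <- c(out, id)
    } else {
      stack <- c(ch, stack)
    }
  }
  out
}

#' Issue the next palette color
#'
#' Colors are issued in queue order and the queue rotates, so the default
#' six-color palette yields indices 0,1,2,3,4,5,0,... A color returned to the
#' palette by a collapse is re-issued first.
#'
#' @param s a [ViewState-class].
#' @return list with `state` (updated [ViewState-class]) and `color`
#'   (0-based index).
#' @export
nextColor <- function(s) {
  stopifnot(is(s, "ViewState"))
  q <- s@palette@queue
  idx <- q[1L]
  s@palette@queue <- c(q[-1L], idx)
  list(state = s, color = idx)
}

#' Paint a subtree
#'
#' Assigns a palette color to a visible node; in color resolution the nearest
#' painted ancestor wins, so painting a node recolors its whole visible
#' subtree except where a descendant carries its own paint. Without an
#' explicit `color`, the palette cursor's color is issued. Repainting a
#' painted node replaces its color (keeping its legend position).
#'
#' @param s a [ViewState-class].
#' @param id a visible node id (not strictly inside a collapsed subtree).
#' @param color optional 0-based palette index.
#' @return the updated [ViewState-class].
#' @export
paintNode <- function(s, id, color = NULL) {
  stopifnot(is(s, "ViewState"))
  .checkNode(s@hierarchy, id)
  hid <- .hiddenBy(s, id)
  if (!is.na(hid)) {
    stop(sprintf("node '%s' is hidden inside collapsed subtree '%s'", id, hid),
         call. = FALSE)
  }
  if (is.null(color)) {
    nc <- nextColor(s)
    s <- nc$state
    color <- nc$color
  } else {
    color <- as.integer(color)
    if (is.na(color) || color < 0L || color >= length(s@palette@colors)) {
      stop(sprintf("color index %s out of range [0, %d)", color,
                   length(s@palette@colors)), call. = FALSE)
    }
  }
  i <- match(id, s@paints$node)
  if (!is.na(i)) {
    s@paints$color[i] <- color
  } else {
    s@paints <- rbind(s@paints, data.frame(node = id, color = color,
                                           seq = s@counter, stringsAsFactors = FALSE))
    s@counter <- s@counter + 1L
  }
  s
}

#' Remove a paint
#'
#' @param s a [ViewState-class].
#' @param id a painted node id (active paint); unknown paints are a no-op.
#' @return the updated [ViewState-class].
#' @export
unpaintNode <- function(s, id) {
  stopifnot(is(s, "ViewState"))
  s@paints <- s@paints[s@paints$node != id, , drop = FALSE]
  s
}

#' Freeze or thaw the view
#'
#' The frozen flag mirrors the interactive freeze-for-export toggle; it is
#' carried through serialization but does not gate operations.
#'
#' @param s a [ViewState-class].
#' @param frozen logical.
#' @return the updated [ViewState-class].
#' @export
freezeView <- function(s, frozen = TRUE) {
  stopifnot(is(s, "ViewState"))
  s@frozen <- isTRUE(frozen)
  s
}

# resolved color for one visible node: own paint, else nearest painted
# visible ancestor, else NA (neutral)
.resolveColor <- function(s, id) {
  chain <- c(id, .ancestors(s@hierarchy, id))
  hit <- match(chain, s@paints$node)
  hit <- hit[!is.na(hit)]
  if (length(hit)) s@paints$color[hit[1L]] else NA_integer_
}

#' Aggregate an abundance table to the visible frontier
#'
#' A collapsed node's column is the sum of its descendant leaves' columns;
#' per-sample totals are conserved exactly. Each effective leaf also carries
#' its resolved paint color (nearest painted ancestor wins).
#'
#' @param a an [AbundanceTable-class]; must validate cleanly against the
#'   state's hierarchy.
#' @param s a [ViewState-class].
#' @return an [EffectiveComposition-class].
#' @export
aggregateComposition <- function(a, s) {
  stopifnot(is(a, "AbundanceTable"), is(s, "ViewState"))
  h <- s@hierarchy
  rep <- validateAbundance(h, a)
  if (!rep@ok) {
    stop(sprintf(
      "abundance does not validate against the hierarchy (missing: %s; extra: %s; negatives: %d)",
      paste(rep@missingColumns, collapse = ","), paste(rep@extraColumns, collapse = ","),
      nrow(rep@negatives)), call. = FALSE)
  }
  v <- abundanceValues(rep@abundance)
  lab <- nodeLabels(h)
  eff <- effectiveLeaves(s)
  cols <- lapply(eff, function(id) {
    under <- leavesUnder(h, id)
    sub <- v[, lab[under], drop = FALSE]
    if (ncol(sub) == 1L) sub[, 1L] else rowSums(sub)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(v), eff)
  colorOf <- vapply(eff, function(id) .resolveColor(s, id), integer(1))
  new("EffectiveComposition", values = m, colorOf = stats::setNames(colorOf, eff),
      labels = stats::setNames(unname(lab[eff]), eff))
}

setMethod("show", "EffectiveComposition", function(object) {
  cat(sprintf("EffectiveComposition: %d samples x %d effective leaves (%d painted)\n",
              nrow(object@values), ncol(object@values), sum(!is.na(object@colorOf))))
})

#' Legend of painted subtrees
#'
#' One entry per active paint, labeled by the painted node's label, ordered by
#' paint insertion. Suspended paints (inside collapsed subtrees) are excluded.
#'
#' @param s a [ViewState-class].
#' @return data.frame with columns `node`, `label`, `color` (0-based index).
#' @export
legendEntries <- function(s) {
  stopifnot(is(s, "ViewState"))
  p <- activePaints(s)
  data.frame(node = p$node,
             label = unname(nodeLabels(s@hierarchy)[p$node]),
             color = p$color, stringsAsFactors = FALSE)
}

## ---- Serialization and replay ---------------------------------------------

#' Serialize a view state to JSON
#'
#' Captures collapsed nodes, active and suspended paints, palette colors and
#' queue, and the frozen flag, so a scripted run is fully reproducible.
#'
#' @param s a [ViewState-class].
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
writeViewState <- function(s, path = NULL) {
  stopifnot(is(s, "ViewState"))
  obj <- list(
    collapsed = s@collapsed,
    paints = s@paints,
    suspended = s@suspended,
    palette = list(colors = s@palette@colors, queue = s@palette@queue),
    frozen = s@frozen,
    counter = s@counter)
  json <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Restore a view state from JSON
#'
#' @param path JSON file (or JSON string) produced by [writeViewState()].
#' @param h the [Hierarchy-class] to bind the state to.
#' @return a [ViewState-class].
#' @export
readViewState <- function(path, h) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  asPaints <- function(x) {
    if (is.null(x) || length(x) == 0L || (is.data.frame(x) && nrow(x) == 0L)) {
      return(.emptyPaints())
    }
    data.frame(node = as.character(x$node), color = as.integer(x$color),
               seq = as.integer(x$seq), stringsAsFactors = FALSE)
  }
  pal <- new("Palette", colors = as.character(obj$palette$colors),
             queue = as.integer(obj$palette$queue))
  s <- new("ViewState", hierarchy = h,
           collapsed = as.character(obj$collapsed %||% character(0)),
           paints = asPaints(obj$paints), suspended = asPaints(obj$suspended),
           palette = pal, frozen = isTRUE(obj$frozen),
           counter = as.integer(obj$counter %||% 1L))
  validObject(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay an interaction event log
#'
#' Deterministically reproduces an interactive session from an explicit event
#' list: each event is a list with `op` in `"collapse"`, `"expand"`,
#' `"paint"`, `"unpaint"`, `"nextColor"`, `"freeze"` and, where relevant, a
#' `node` and an optional `color`.
#'
#' @param s a starting [ViewState-class].
#' @param events list of event lists.
#' @return the final [ViewState-class].
#' @export
replayEvents <- function(s, events) {
  for (ev in events) {
    s <- switch(ev$op,
      collapse = collapseNode(s, ev$node),
      expand = expandNode(s, ev$node),
      paint = paintNode(s, ev$node, ev$color),
      unpaint = unpaintNode(s, ev$node),
      nextColor = nextColor(s)$state,
      freeze = freezeView(s, ev$frozen %||% TRUE),
      stop(sprintf("unknown event op '%s'", ev$op), call. = FALSE))
  }
  s
}
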