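#' @include AllClasses.R view-state.R
NULL

#' Construct a canvas specification
#'
#' @param width,height canvas size in abstract units (default 800 x 500).
#' @param treeFraction,barFraction width fractions of the tree and bar panels
#'   (defaults 0.35 and 0.55; the remaining 0.10 is the gutter).
#' @param margin outer margin (default 20).
#' @param barGapFraction fraction of each sample slot left as gap (default 0.15).
#' @return a [CanvasSpec-class].
#' @export
canvasSpec <- function(width = 800, height = 500, treeFraction = 0.35,
                       barFraction = 0.55, margin = 20, barGapFraction = 0.15) {
  new("CanvasSpec", width = width, height = height, treeFraction = treeFraction,
      barFraction = barFraction, margin = margin, barGapFraction = barGapFraction)
}

#' Lay out the tree panel
#'
#' Positions only the visible nodes (the effective-leaf frontier plus its
#' ancestors); the layout is recomputed from the frontier so collapsing frees
#' space for the remaining subtrees. Frontier nodes sit at evenly spaced band
#' centers top to bottom; an internal node's y is the mean of its children's
#' y and its x is proportional to its topological depth (cladogram: branch
#' lengths are ignored).
#'
#' @param s a [ViewState-class].
#' @param canvas a [CanvasSpec-class].
#' @return a [TreeLayout-class].
#' @export
layoutTree <- function(s, canvas = canvasSpec()) {
  stopifnot(is(s, "ViewState"), is(canvas, "CanvasSpec"))
  h <- s@hierarchy
  eff <- effectiveLeaves(s)
  visible <- unique(c(unlist(lapply(eff, function(id) rev(.ancestors(h, id)))), eff))
  # keep pre-order
  visible <- h@nodes$id[h@nodes$id %in% visible]
  par <- stats::setNames(h@nodes$parent, h@nodes$id)
  depth <- vapply(visible, function(id) length(.ancestors(h, id)), integer(1))
  maxDepth <- max(depth)
  innerW <- canvas@width - 2 * canvas@margin
  innerH <- canvas@height - 2 * canvas@margin
  treeW <- canvas@treeFraction * innerW
  x <- canvas@margin + if (maxDepth > 0) depth / maxDepth * treeW else rep(0, length(depth))
  band <- innerH / length(eff)
  y <- stats::setNames(rep(NA_real_, length(visible)), visible)
  y[eff] <- canvas@margin + (seq_along(eff) - 0.5) * band
  # internal y bottom-up: reverse pre-order guarantees children before parents
  kids <- .childMap(h)
  for (id in rev(visible)) {
    if (is.na(y[[id]])) y[[id]] <- mean(y[kids[[id]]])
  }
  lab <- nodeLabels(h)
  nodes <- data.frame(
    id = visible, label = unname(lab[visible]),
    x = unname(x), y = unname(y[visible]), depth = unname(depth),
    collapsed = visible %in% s@collapsed, frontier = visible %in% eff,
    preorder = match(visible, h@nodes$id), stringsAsFactors = FALSE)
  child <- visible[visible != h@root]
  edges <- data.frame(
    parent = unname(par[child]), child = child,
    x1 = nodes$x[match(unname(par[child]), visible)],
    y1 = nodes$y[match(unname(par[child]), visible)],
    x2 = nodes$x[match(child, visible)],
    y2 = nodes$y[match(child, visible)], stringsAsFactors = FALSE)
  new("TreeLayout", nodes = nodes, edges = edges, frontier = eff, canvas = canvas)
}

setMethod("show", "TreeLayout", function(object) {
  cat(sprintf("TreeLayout: %d visible nodes, %d edges, %d frontier leaves\n",
              nrow(object@nodes), nrow(object@edges), length(object@frontier)))
})

#' Lay out the bar panel
#'
#' One vertical bar per arranged sample, segments stacked top to bottom in
#' effective-leaf order so the top segment matches the tree's top leaf. In
#' normalized mode each bar's segment heights sum to the panel height; in raw
#' mode heights share a global scale set by the largest arranged sample total,
#' so bar totals may differ. Zero-valued segments are kept with zero height.
#'
#' @param e an [EffectiveComposition-class].
#' @param arr an [Arrangement-class]; its samples must exist in `e`.
#' @param canvas a [CanvasSpec-class].
#' @param normalize logical (default `TRUE`).
#' @return a [BarLayout-class].
#' @export
layoutBars <- function(e, arr, canvas = canvasSpec(), normalize = TRUE) {
  stopifnot(is(e, "EffectiveComposition"), is(arr, "Arrangement"),
            is(canvas, "CanvasSpec"))
  samples <- orderedSamples(arr)
  unknown <- setdiff(samples, rownames(e@values))
  if (length(unknown)) {
    stop(sprintf("arranged sample(s) not in composition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  eff <- colnames(e@values)
  innerW <- canvas@width - 2 * canvas@margin
  innerH <- canvas@height - 2 * canvas@margin
  barW <- canvas@barFraction * innerW
  barX0 <- canvas@margin + innerW - barW
  slot <- barW / length(samples)
  gap <- slot * canvas@barGapFraction
  bx <- barX0 + (seq_along(samples) - 1) * slot + gap / 2
  bars <- data.frame(sample = samples, x = bx, width = slot - gap,
                     stringsAsFactors = FALSE)
  totals <- rowSums(e@values)[samples]
  segs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    v <- e@values[samples[i], ]
    hgt <- if (normalize) {
      if (totals[i] > 0) v / totals[i] * innerH else rep(0, length(v))
    } else {
      v * (innerH / max(totals))
    }
    yTop <- canvas@margin + c(0, cumsum(hgt)[-length(hgt)])
    segs[[i]] <- data.frame(
      sample = samples[i], leaf = eff, x = bx[i], y = yTop,
      width = slot - gap, height = unname(hgt),
      color = unname(e@colorOf[eff]), stringsAsFactors = FALSE)
  }
  new("BarLayout", bars = bars, segments = do.call(rbind, segs),
      frontier = eff, normalized = isTRUE(normalize), canvas = canvas)
}

setMethod("show", "BarLayout", function(object) {
  cat(sprintf("BarLayout: %d bars x %d segments (%s mode)\n",
              nrow(object@bars), length(object@frontier),
              if (object@normalized) "normalized" else "raw"))
})

## ---- Nearest-node hover partition ------------------------------------------

# k-d tree over 2-d sites; returns nested list of (index, axis, left, right)
.kdBuild <- function(pts, idx, depth = 0L) {
  if (!length(idx)) return(NULL)
  ax <- depth %% 2L + 1L
  o <- idx[order(pts[idx, ax], idx)]
  m <- (length(o) + 1L) %/% 2L
  list(i = o[m], axis = ax,
       left = .kdBuild(pts, o[seq_len(m - 1L)], depth + 1L),
       right = .kdBuild(pts, o[m + seq_len(length(o) - m)], depth + 1L))
}

# nearest site; ties resolved toward the smaller pre-order index
.kdNearest <- function(tree, pts, pre, q) {
  best <- list(d2 = Inf, pre = Inf, i = NA_integer_)
  consider <- function(i) {
    d2 <- (pts[i, 1L] - q[1L])^2 + (pts[i, 2L] - q[2L])^2
    if (d2 < best$d2 || (d2 == best$d2 && pre[i] < best$pre)) {
      best <<- list(d2 = d2, pre = pre[i], i = i)
    }
  }
  walk <- function(node) {
    if (is.null(node)) return(invisible(NULL))
    consider(node$i)
    ax <- node$axis
    delta <- q[ax] - pts[node$i, ax]
    first <- if (delta < 0) node$left else node$right
    second <- if (delta < 0) node$right else node$left
    walk(first)
    if (delta^2 <= best$d2) walk(second)  # <=: the far side may hold a tie with smaller pre-order
    invisible(NULL)
  }
  walk(tree)
  best$i
}

#' Build the hover-region map of a tree layout
#'
#' Answers "which node is nearest to this point": the Voronoi partition of the
#' node sites (the dual of the Delaunay triangulation the interactive tool
#' uses for hover targeting), implemented as a k-d tree. Every node's own site
#' maps to itself; ties go to the smaller pre-order index.
#'
#' @param t a [TreeLayout-class] with at least one visible node.
#' @return a [HoverRegionMap-class]; query it with [queryHover()].
#' @export
hoverMap <- function(t) {
  stopifnot(is(t, "TreeLayout"), nrow(t@nodes) >= 1L)
  pts <- cbind(t@nodes$x, t@nodes$y)
  new("HoverRegionMap", ids = t@nodes$id, sites = pts,
      preorder = as.integer(t@nodes$preorder),
      kdtree = .kdBuild(pts, seq_len(nrow(pts))))
}

#' Query the hover-region map
#'
#' @param map a [HoverRegionMap-class].
#' @param x,y query coordinates (vectors of equal length).
#' @return node ids of the nearest sites.
#' @export
queryHover <- function(map, x, y) {
  stopifnot(is(map, "HoverRegionMap"), length(x) == length(y))
  vapply(seq_along(x), function(k) {
    map@ids[.kdNearest(map@kdtree, map@sites, map@preorder, c(x[k], y[k]))]
  }, character(1))
}

setMethod("show", "HoverRegionMap", function(object) {
  cat(sprintf("HoverRegionMap: %d sites\n", length(object@ids)))
})

#' Serialize layouts for external renderers
#'
#' Writes the tree layout, bar layout and legend as one JSON document so an
#' external renderer can reproduce the view.
#'
#' @param t a [TreeLayout-class].
#' @param b a [BarLayout-class].
#' @param legend data.frame from [legendEntries()].
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
layoutToJson <- function(t, b, legend, path = NULL) {
  obj <- list(
    canvas = list(width = t@canvas@width, height = t@canvas@height),
    tree = list(nodes = t@nodes, edges = t@edges, frontier = t@frontier),
    bars = list(bars = b@bars, segments = b@segments, normalized = b@normalized),
    legend = legend)
  json <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
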