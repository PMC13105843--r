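#' @include AllClasses.R layout.R
NULL

#' Construct a style configuration
#'
#' @param palette hex colors for paints (default: the six-color palette).
#' @param neutralColor fill for unpainted segments (default `#cccccc`).
#' @param nodeFontSize,sampleFontSize,legendFontSize font sizes (canvas units).
#' @param edgeStrokeWidth stroke width of tree edges and node borders.
#' @param collapsedStrokeMultiplier border multiplier for collapsed nodes.
#' @param labelMode `"legend"` (separate legend block) or `"on-subtree"`
#'   (legend labels drawn at the painted subtree roots).
#' @param hideSampleLabels suppress sample labels beneath the bars.
#' @param canvas a [CanvasSpec-class].
#' @return a [StyleConfig-class].
#' @export
styleConfig <- function(palette = paletteColors(defaultPalette()),
                        neutralColor = "#cccccc",
                        nodeFontSize = 10, sampleFontSize = 9, legendFontSize = 11,
                        edgeStrokeWidth = 1, collapsedStrokeMultiplier = 3,
                        labelMode = "legend", hideSampleLabels = FALSE,
                        canvas = canvasSpec()) {
  new("StyleConfig", palette = palette, neutralColor = neutralColor,
      nodeFontSize = nodeFontSize, sampleFontSize = sampleFontSize,
      legendFontSize = legendFontSize, edgeStrokeWidth = edgeStrokeWidth,
      collapsedStrokeMultiplier = collapsedStrokeMultiplier,
      labelMode = labelMode, hideSampleLabels = hideSampleLabels, canvas = canvas)
}

.fmt <- function(x) sprintf("%.2f", x)

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a laid-out view to SVG
#'
#' Deterministic static export: tree edges and nodes (collapsed nodes with a
#' thicker border), stacked bars (zero-height segments omitted; painted
#' segments filled with their palette color, unpainted with the neutral
#' gray), sample labels, and the legend of painted subtree root labels.
#' Attribute order and number formatting are fixed, so identical inputs give
#' byte-identical output.
#'
#' @param t a [TreeLayout-class].
#' @param b a [BarLayout-class] computed from the same view state (the
#'   frontiers must agree).
#' @param legend data.frame from [legendEntries()].
#' @param style a [StyleConfig-class].
#' @return an [SvgDocument-class].
#' @export
renderSvg <- function(t, b, legend, style = styleConfig()) {
  stopifnot(is(t, "TreeLayout"), is(b, "BarLayout"), is(style, "StyleConfig"))
  if (!identical(t@frontier, b@frontier)) {
    stop("tree and bar layouts disagree on the effective-leaf frontier", call. = FALSE)
  }
  if (nrow(legend) && max(legend$color) >= length(style@palette)) {
    stop("legend color index outside the style palette", call. = FALSE)
  }
  cv <- t@canvas
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">",
            .fmt(cv@width), .fmt(cv@height), .fmt(cv@width), .fmt(cv@height)))

  out <- c(out, "<g id=\"tree-edges\">")
  e <- t@edges
  if (nrow(e)) {
    out <- c(out, sprintf(
      "<line id=\"tree-edge-%s-%s\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#555555\" stroke-width=\"%s\"/>",
      e$parent, e$child, .fmt(e$x1), .fmt(e$y1), .fmt(e$x2), .fmt(e$y2),
      .fmt(style@edgeStrokeWidth)))
  }
  out <- c(out, "</g>", "<g id=\"tree-nodes\">")
  nd <- t@nodes
  sw <- ifelse(nd$collapsed, style@edgeStrokeWidth * style@collapsedStrokeMultiplier,
               style@edgeStrokeWidth)
  out <- c(out, sprintf(
    "<circle id=\"tree-node-%s\" cx=\"%s\" cy=\"%s\" r=\"3.00\" fill=\"#555555\" stroke=\"#555555\" stroke-width=\"%s\"/>",
    nd$id, .fmt(nd$x), .fmt(nd$y), .fmt(sw)))
  out <- c(out, "</g>", "<g id=\"tree-labels\">")
  fr <- nd[nd$frontier, , drop = FALSE]
  out <- c(out, sprintf(
    "<text id=\"tree-label-%s\" x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\">%s</text>",
    fr$id, .fmt(fr$x + 5), .fmt(fr$y + style@nodeFontSize / 3),
    .fmt(style@nodeFontSize), .xmlEscape(fr$label)))
  out <- c(out, "</g>", "<g id=\"bars\">")
  seg <- b@segments[b@segments$height > 0, , drop = FALSE]
  if (nrow(seg)) {
    fill <- ifelse(is.na(seg$color), style@neutralColor, style@palette[seg$color + 1L])
    out <- c(out, sprintf(
      "<rect id=\"bar-%s-%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"#ffffff\" stroke-width=\"0.30\"/>",
      seg$sample, seg$leaf, .fmt(seg$x), .fmt(seg$y), .fmt(seg$width),
      .fmt(seg$height), fill))
  }
  out <- c(out, "</g>")

  if (!style@hideSampleLabels && nrow(b@bars)) {
    out <- c(out, "<g id=\"sample-labels\">")
    out <- c(out, sprintf(
      "<text id=\"sample-label-%s\" x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\" text-anchor=\"middle\">%s</text>",
      b@bars$sample, .fmt(b@bars$x + b@bars$width / 2),
      .fmt(cv@height - cv@margin + style@sampleFontSize),
      .fmt(style@sampleFontSize), .xmlEscape(b@bars$sample)))
    out <- c(out, "</g>")
  }

  if (nrow(legend)) {
    out <- c(out, "<g id=\"legend\">")
    if (style@labelMode == "on-subtree") {
      # label text sits at the painted subtree root's coordinates
      pos <- match(legend$node, nd$id)
      out <- c(out, sprintf(
        "<text id=\"legend-%d\" x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\" fill=\"%s\">%s</text>",
        seq_len(nrow(legend)), .fmt(nd$x[pos]), .fmt(nd$y[pos] - 4),
        .fmt(style@legendFontSize), style@palette[legend$color + 1L],
        .xmlEscape(legend$label)))
    } else {
      lh <- style@legendFontSize * 1.5
      ly <- cv@margin + (seq_len(nrow(legend)) - 1) * lh
      lx <- cv@margin + 4
      out <- c(out, sprintf(
        "<rect id=\"legend-%d-swatch\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
        seq_len(nrow(legend)), .fmt(lx), .fmt(ly), .fmt(style@legendFontSize),
        .fmt(style@legendFontSize), style@palette[legend$color + 1L]))
      out <- c(out, sprintf(
        "<text id=\"legend-%d\" x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\">%s</text>",
        seq_len(nrow(legend)), .fmt(lx + style@legendFontSize + 4),
        .fmt(ly + style@legendFontSize - 2), .fmt(style@legendFontSize),
        .xmlEscape(legend$label)))
    }
    out <- c(out, "</g>")
  }

  out <- c(out, "</svg>")
  new("SvgDocument", content = paste(out, collapse = "\n"))
}

#' @describeIn SvgDocument-class the SVG text.
#' @param x an [SvgDocument-class].
#' @export
svgContent <- function(x) {
  stopifnot(is(x, "SvgDocument"))
  x@content
}

#' Write an SVG document to a file
#'
#' @param x an [SvgDocument-class].
#' @param path output path.
#' @return `path` invisibly.
#' @export
saveSvg <- function(x, path) {
  stopifnot(is(x, "SvgDocument"))
  writeLines(x@content, path, useBytes = TRUE)
  invisible(path)
}

setMethod("show", "SvgDocument", function(object) {
  nRect <- lengths(regmatches(object@content, gregexpr("<rect id=\"bar-", object@content)))
  cat(sprintf("SvgDocument: %d characters, %d bar rectangles\n",
              nchar(object@content), nRect))
})

#' Render a view in one call
#'
#' Convenience pipeline: aggregate the abundance to the visible frontier, lay
#' out both panels, and render. Identical to composing
#' [aggregateComposition()], [layoutTree()], [layoutBars()] and [renderSvg()]
#' by hand.
#'
#' @param a an [AbundanceTable-class].
#' @param s a [ViewState-class].
#' @param arr an [Arrangement-class]; default is the input row order.
#' @param style a [StyleConfig-class].
#' @param normalize passed to [layoutBars()].
#' @return an [SvgDocument-class].
#' @export
renderView <- function(a, s, arr = orderByRows(a), style = styleConfig(),
                       normalize = TRUE) {
  e <- aggregateComposition(a, s)
  t <- layoutTree(s, style@canvas)
  b <- layoutBars(e, arr, style@canvas, normalize = normalize)
  renderSvg(t, b, legendEntries(s), style)
}
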