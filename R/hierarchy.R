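#' @include AllClasses.R AllGenerics.R
NULL

.newHierarchy <- function(nodes) {
  rownames(nodes) <- NULL
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1L) stop("exactly one root required", call. = FALSE)
  new("Hierarchy", nodes = nodes, root = root,
      leafOrder = .computeLeafOrder(nodes, root))
}

# depth-first left-to-right leaf sequence, child order = row order
.computeLeafOrder <- function(nodes, root) {
  kids <- split(seq_len(nrow(nodes)), factor(nodes$parent, levels = nodes$id))
  out <- character(0)
  stack <- root
  while (length(stack)) {
    id <- stack[[1L]]
    stack <- stack[-1L]
    ch <- nodes$id[kids[[id]]]
    if (length(ch) == 0L) out <- c(out, id) else stack <- c(ch, stack)
  }
  out
}

.childMap <- function(h) {
  nd <- h@nodes
  idx <- split(seq_len(nrow(nd)), factor(nd$parent, levels = nd$id))
  lapply(idx, function(i) nd$id[i])
}

.checkNode <- function(h, id) {
  if (!is.character(id) || length(id) != 1L || !id %in% h@nodes$id) {
    stop(sprintf("unknown node id: %s", paste(id, collapse = ", ")), call. = FALSE)
  }
  invisible(id)
}

# all proper ancestors, nearest first
.ancestors <- function(h, id) {
  par <- stats::setNames(h@nodes$parent, h@nodes$id)
  out <- character(0)
  p <- par[[id]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- par[[p]]
  }
  out
}

# ids in the subtree rooted at id (including id), pre-order
.subtreeIds <- function(h, id) {
  kids <- .childMap(h)
  out <- character(0)
  stack <- id
  while (length(stack)) {
    nid <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, nid)
    stack <- c(kids[[nid]], stack)
  }
  out
}

#' @describeIn Hierarchy-class node ids in pre-order.
#' @export
setMethod("nodeIds", "Hierarchy", function(x) x@nodes$id)

#' @describeIn Hierarchy-class display labels, named by node id.
#' @export
setMethod("nodeLabels", "Hierarchy", function(x) {
  stats::setNames(x@nodes$label, x@nodes$id)
})

#' @describeIn Hierarchy-class id of the root.
#' @export
setMethod("rootId", "Hierarchy", function(x) x@root)

#' @describeIn Hierarchy-class leaf ids in depth-first left-to-right order.
#' @export
setMethod("leafIds", "Hierarchy", function(x) x@leafOrder)

#' @describeIn Hierarchy-class ordered children of `id`.
#' @export
setMethod("childrenOf", "Hierarchy", function(x, id) {
  .checkNode(x, id)
  x@nodes$id[!is.na(x@nodes$parent) & x@nodes$parent == id]
})

#' @describeIn Hierarchy-class parent of `id` (`NA` for the root).
#' @export
setMethod("parentOf", "Hierarchy", function(x, id) {
  .checkNode(x, id)
  x@nodes$parent[match(id, x@nodes$id)]
})

#' @describeIn Hierarchy-class is `id` a leaf?
#' @export
setMethod("isLeaf", "Hierarchy", function(x, id) {
  .checkNode(x, id)
  id %in% x@leafOrder
})

setMethod("show", "Hierarchy", function(object) {
  cat(sprintf("Hierarchy: %d nodes, %d leaves, root '%s'\n",
              nrow(object@nodes), length(object@leafOrder), object@root))
  cat("  leaves:", paste(utils::head(nodeLabels(object)[object@leafOrder], 8), collapse = ", "),
      if (length(object@leafOrder) > 8) "...\n" else "\n")
})

## ---- Newick ----------------------------------------------------------------

# Recursive-descent Newick reader. A hand-written scanner is used so that
# syntax errors carry a character offset and unlabeled internal nodes receive
# reproducible pre-order ids.
#' Parse a Newick string into a [Hierarchy-class]
#'
#' Accepts standard Newick with optional internal labels, quoted labels and
#' branch lengths. Branch lengths are parsed and stored but unused by the
#' rank-based layout. Unlabeled internal nodes receive generated ids
#' (`node_0001`, numbered in pre-order); non-binary nodes are accepted.
#'
#' @param text a single Newick string (terminating `;`).
#' @return a [Hierarchy-class].
#' @examples
#' h <- parseNewick("((A,B),C);")
#' leafIds(h)
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(s)
  pos <- 1L
  perr <- function(msg, at = pos) {
    stop(sprintf("Newick parse error at character %d: %s", at, msg), call. = FALSE)
  }
  skipws <- function() {
    while (pos <= n && s[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
  }
  peek <- function() if (pos <= n) s[pos] else ""
  readLabel <- function() {
    skipws()
    if (peek() == "'") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > n) perr("unterminated quoted label", start)
        if (s[pos] == "'") {
          if (pos + 1L <= n && s[pos + 1L] == "'") {  # escaped quote
            out <- c(out, "'")
            pos <<- pos + 2L
          } else {
            pos <<- pos + 1L
            break
          }
        } else {
          out <- c(out, s[pos])
          pos <<- pos + 1L
        }
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (pos <= n && !s[pos] %in% c(",", "(", ")", ":", ";", " ", "\t", "\n", "\r")) {
        out <- c(out, s[pos])
        pos <<- pos + 1L
      }
      paste(out, collapse = "")
    }
  }
  readLength <- function() {
    skipws()
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    skipws()
    out <- character(0)
    while (pos <= n && s[pos] %in% c(as.character(0:9), ".", "-", "+", "e", "E")) {
      out <- c(out, s[pos])
      pos <<- pos + 1L
    }
    v <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (is.na(v)) perr("invalid branch length")
    v
  }
  readClade <- function() {
    skipws()
    if (peek() == "(") {
      open <- pos
      pos <<- pos + 1L
      children <- list(readClade())
      skipws()
      while (peek() == ",") {
        pos <<- pos + 1L
        children[[length(children) + 1L]] <- readClade()
        skipws()
      }
      if (peek() != ")") perr(sprintf("expected ')' to close '(' at character %d", open))
      pos <<- pos + 1L
      list(label = readLabel(), length = readLength(), children = children)
    } else {
      at <- pos
      lab <- readLabel()
      if (!nzchar(lab)) perr("expected a label", at)
      list(label = lab, length = readLength(), children = list())
    }
  }
  skipws()
  if (pos > n) perr("empty input")
  tree <- readClade()
  skipws()
  if (peek() != ";") perr("expected ';'")
  pos <- pos + 1L
  skipws()
  if (pos <= n) perr("trailing characters after ';'")

  # flatten in pre-order
  rows <- list()
  counter <- 0L
  used <- new.env(parent = emptyenv())
  visit <- function(node, parent) {
    counter <<- counter + 1L
    if (length(node$children)) {
      id <- node$label
      if (!nzchar(id) || !is.null(used[[id]])) id <- sprintf("node_%04d", counter)
      lab <- if (nzchar(node$label)) node$label else id
    } else {
      id <- node$label
      lab <- node$label
      if (!is.null(used[[id]])) {
        # collect all duplicates for the error message below
      }
    }
    used[[id]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, label = lab, parent = if (is.null(parent)) NA_character_ else parent,
      rank = NA_character_, length = node$length, stringsAsFactors = FALSE)
    for (ch in node$children) visit(ch, id)
  }
  visit(tree, NULL)
  nodes <- do.call(rbind, rows)
  leaves <- setdiff(nodes$id, nodes$parent)
  dup <- unique(nodes$label[nodes$id %in% leaves][duplicated(nodes$label[nodes$id %in% leaves])])
  if (length(dup)) {
    stop(sprintf("duplicate leaf labels: %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop(sprintf("duplicate node ids: %s",
                 paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")), call. = FALSE)
  }
  .newHierarchy(nodes)
}

#' Serialize a [Hierarchy-class] to Newick
#'
#' Round-trips with [parseNewick()]: topology, labels and leaf order are
#' reproduced exactly. Labels containing Newick metacharacters are quoted;
#' generated internal ids (`node_NNNN`) are omitted so re-parsing regenerates
#' them identically. Branch lengths are written when any is present.
#'
#' @param h a [Hierarchy-class].
#' @return a single Newick string.
#' @export
writeNewick <- function(h) {
  stopifnot(is(h, "Hierarchy"))
  nd <- h@nodes
  kids <- .childMap(h)
  withLen <- any(!is.na(nd$length))
  quoteLab <- function(x) {
    if (grepl("[](),:;'[ \t]", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  emit <- function(id) {
    i <- match(id, nd$id)
    ch <- kids[[id]]
    lab <- nd$label[i]
    lenStr <- if (withLen && !is.na(nd$length[i])) sprintf(":%s", format(nd$length[i], digits = 15)) else ""
    if (length(ch) == 0L) {
      paste0(quoteLab(lab), lenStr)
    } else {
      showLab <- if (grepl("^node_[0-9]+$", lab)) "" else quoteLab(lab)
      paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")", showLab, lenStr)
    }
  }
  paste0(emit(h@root), ";")
}

## ---- Taxonomy table --------------------------------------------------------

#' Convert a taxonomy rank table into a [Hierarchy-class]
#'
#' Each row is one taxon; columns are rank names ordered coarse to fine; the
#' finest non-missing cell of a row is the leaf. Missing cells (`NA` or `""`)
#' are skipped, so a row's path is its non-missing cells in rank order — no
#' "unclassified" placeholder nodes are inserted. Identical names under
#' different parents become distinct nodes (internal ids are the full path
#' joined with `|`; the display label stays the cell value). Children are
#' ordered by first appearance in the table. If the coarsest rank has a single
#' value it becomes the root; otherwise a synthetic root labeled `"Root"` is
#' added.
#'
#' @param tab data.frame of character columns (rank names as column names).
#' @return a [Hierarchy-class]; leaf ids equal the leaf (finest cell) labels.
#' @examples
#' tab <- data.frame(Kingdom = "K1", Phylum = c("P1", "P1", "P2"),
#'                   Order = c("O1", "O2", "O3"))
#' leafIds(taxonomyToTree(tab))
#' @export
taxonomyToTree <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty taxonomy table", call. = FALSE)
  ranks <- colnames(tab)
  cells <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.character(unlist(tab[i, ], use.names = FALSE))
    keep <- !is.na(v) & nzchar(v)
    list(values = v[keep], ranks = ranks[keep])
  })
  if (any(vapply(cells, function(p) length(p$values) == 0L, logical(1)))) {
    stop("taxonomy rows with no non-missing cells", call. = FALSE)
  }
  leaves <- vapply(cells, function(p) p$values[length(p$values)], character(1))
  if (anyDuplicated(leaves)) {
    stop(sprintf("duplicate leaf labels: %s",
                 paste(unique(leaves[duplicated(leaves)]), collapse = ", ")), call. = FALSE)
  }
  top <- unique(vapply(cells, function(p) p$values[1L], character(1)))
  synthRoot <- length(top) > 1L

  rows <- list()
  seen <- new.env(parent = emptyenv())
  addNode <- function(id, label, parent, rank) {
    if (!is.null(seen[[id]])) return(invisible(NULL))
    seen[[id]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, label = label, parent = parent, rank = rank,
      length = NA_real_, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  if (synthRoot) addNode("Root", "Root", NA_character_, NA_character_)
  for (p in cells) {
    m <- length(p$values)
    parent <- if (synthRoot) "Root" else NA_character_
    path <- character(0)
    for (j in seq_len(m)) {
      path <- c(path, p$values[j])
      if (j == m) {
        id <- p$values[j]  # leaf: id is the (unique) leaf label, the join key
      } else {
        id <- paste(path, collapse = "|")
      }
      addNode(id, p$values[j], parent, p$ranks[j])
      parent <- id
    }
  }
  nodes <- do.call(rbind, rows)
  if (anyDuplicated(nodes$id)) {
    stop("taxonomy produces colliding node ids", call. = FALSE)
  }
  # rows were appended in first-appearance order per parent but not pre-order;
  # reorder depth-first preserving sibling order
  kids <- split(seq_len(nrow(nodes)), factor(nodes$parent, levels = nodes$id))
  ord <- integer(0)
  root <- which(is.na(nodes$parent))
  stack <- root
  while (length(stack)) {
    i <- stack[[1L]]
    stack <- stack[-1L]
    ord <- c(ord, i)
    stack <- c(kids[[nodes$id[i]]], stack)
  }
  .newHierarchy(nodes[ord, , drop = FALSE])
}

## ---- Validation ------------------------------------------------------------

#' Validate an abundance table against a hierarchy
#'
#' The leaf labels of the hierarchy must match the abundance columns exactly
#' (as sets) and all values must be non-negative. On success, the returned
#' report carries the abundance table with columns reindexed to leaf order.
#'
#' @param h a [Hierarchy-class].
#' @param a an [AbundanceTable-class].
#' @return a [ValidationReport-class]; problems are the report's content, not
#'   errors.
#' @export
validateAbundance <- function(h, a) {
  stopifnot(is(h, "Hierarchy"), is(a, "AbundanceTable"))
  leafLab <- unname(nodeLabels(h)[h@leafOrder])
  cols <- colnames(a@values)
  missingColumns <- setdiff(leafLab, cols)
  extraColumns <- setdiff(cols, leafLab)
  negIdx <- which(a@values < 0, arr.ind = TRUE)
  negatives <- data.frame(
    sample = rownames(a@values)[negIdx[, 1L]],
    taxon = colnames(a@values)[negIdx[, 2L]],
    value = a@values[negIdx],
    stringsAsFactors = FALSE)
  ok <- length(missingColumns) == 0L && length(extraColumns) == 0L && nrow(negatives) == 0L
  ab <- if (ok) abundanceTable(a@values[, leafLab, drop = FALSE]) else a
  new("ValidationReport", ok = ok, missingColumns = missingColumns,
      extraColumns = extraColumns, negatives = negatives, abundance = ab)
}

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s\n", if (object@ok) "ok" else "NOT ok"))
  if (length(object@missingColumns))
    cat("  leaves missing from columns:", paste(object@missingColumns, collapse = ", "), "\n")
  if (length(object@extraColumns))
    cat("  columns missing from leaves:", paste(object@extraColumns, collapse = ", "), "\n")
  if (nrow(object@negatives))
    cat(sprintf("  %d negative value(s)\n", nrow(object@negatives)))
})

## ---- Search and subtree queries -------------------------------------------

#' Search node labels
#'
#' Case-insensitive substring search across all labels, internal nodes and
#' leaves alike, returned in pre-order. An empty query matches nothing.
#'
#' @param x a [Hierarchy-class].
#' @param query a single string.
#' @return matching node ids (pre-order).
#' @export
setMethod("searchLabels", "Hierarchy", function(x, query) {
  stopifnot(is.character(query), length(query) == 1L)
  if (!nzchar(query)) return(character(0))
  # literal substring match, case-folded
  hit <- grepl(tolower(query), tolower(x@nodes$label), fixed = TRUE)
  x@nodes$id[hit]
})

#' Leaves of a subtree
#'
#' @param x a [Hierarchy-class].
#' @param id a node id; for a leaf, the result is the leaf itself.
#' @return the subtree's leaf ids in leaf order.
#' @export
setMethod("leavesUnder", "Hierarchy", function(x, id) {
  .checkNode(x, id)
  sub <- .subtreeIds(x, id)
  x@leafOrder[x@leafOrder %in% sub]
})
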