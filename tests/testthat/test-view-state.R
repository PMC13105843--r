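test_that("default palette has six colors and the cursor cycles modularly", {
  expect_length(paletteColors(defaultPalette()), 6L)

  s <- viewState(taxonomyToTree(tinyTaxonomy()))
  issued <- integer(0)
  for (i in 1:13) {
    r <- nextColor(s)
    s <- r$state
    issued <- c(issued, r$color)
  }
  expect_identical(issued[1:7], c(0:5, 0L))
  expect_identical(issued[13], 0L)  # 12 mod 6

  s1 <- viewState(taxonomyToTree(tinyTaxonomy()), newPalette("#000000"))
  r1 <- nextColor(s1); r2 <- nextColor(r1$state)
  expect_identical(c(r1$color, r2$color), c(0L, 0L))
})

test_that("collapse merges the frontier, is idempotent, and a leaf collapse is a no-op", {
  h <- taxonomyToTree(tinyTaxonomy())
  s <- collapseNode(viewState(h), "K1|P1")
  expect_identical(effectiveLeaves(s), c("K1|P1", "O3"))
  expect_identical(collapsedNodes(collapseNode(s, "K1|P1")), collapsedNodes(s))
  expect_identical(effectiveLeaves(collapseNode(viewState(h), "O1")), leafIds(h))
  expect_error(collapseNode(s, "ghost"), "unknown node")
})

test_that("a color surviving only in a collapsed subtree returns to the palette", {
  h <- taxonomyToTree(tinyTaxonomy())
  s <- paintNode(viewState(h), "O1")        # issues color 0
  expect_identical(activePaints(s)$color, 0L)
  s <- collapseNode(s, "K1|P1")
  expect_identical(nrow(activePaints(s)), 0L)
  expect_identical(nrow(legendEntries(s)), 0L)        # entry disappears from legend
  expect_identical(nextColor(s)$color, 0L)            # freed color re-issued first
})

test_that("expand restores the previous state: paints, colors, nesting", {
  h <- randomHierarchy(20, seed = 7)
  a <- randomAbundance(h, 4, seed = 7)
  internal <- internalIds(h)
  s <- paintNode(viewState(h), internal[2], 3)
  s <- paintNode(s, leafIds(h)[1], 1)
  before <- aggregateComposition(a, s)
  beforePaints <- activePaints(s)

  n <- internal[2]
  s2 <- expandNode(collapseNode(s, n), n)
  after <- aggregateComposition(a, s2)
  expect_identical(after@values, before@values)
  expect_identical(after@colorOf, before@colorOf)
  expect_identical(activePaints(s2), beforePaints)

  expect_message(expandNode(s, n), "not collapsed")
})

test_that("nested collapsed descendants retain their own state through expand", {
  # K1 > P1 > C1 > {O1,O2}; collapse C1, then P1, then expand P1
  tab <- data.frame(K = "K1", P = c("P1", "P1", "P2"), C = c("C1", "C1", "C2"),
                    O = c("O1", "O2", "O3"), stringsAsFactors = FALSE)
  h <- taxonomyToTree(tab)
  s <- collapseNode(viewState(h), "K1|P1|C1")
  s <- collapseNode(s, "K1|P1")
  expect_identical(effectiveLeaves(s), c("K1|P1", "O3"))
  s <- expandNode(s, "K1|P1")
  expect_identical(effectiveLeaves(s), c("K1|P1|C1", "O3"))
})

test_that("paint-then-collapse-then-expand restores the same color (event replay)", {
  h <- randomHierarchy(30, seed = 3)
  leaf <- leafIds(h)[5]
  enclosing <- rev(pathToRoot(h, leaf))[2]  # parent of the leaf
  events <- list(
    list(op = "paint", node = leaf, color = 4L),
    list(op = "collapse", node = enclosing),
    list(op = "expand", node = enclosing))
  s <- replayEvents(viewState(h), events)
  p <- activePaints(s)
  expect_identical(p$node, leaf)
  expect_identical(p$color, 4L)
})

test_that("effective leaves equal the per-leaf ancestor-scan oracle on random states", {
  for (seed in 1:40) {
    h <- randomHierarchy(sample(3:60, 1L), seed)
    internal <- internalIds(h)
    collapsed <- sample(internal, sample(0:min(6, length(internal)), 1L))
    s <- viewState(h)
    for (id in collapsed) s <- collapseNode(s, id)
    expect_identical(effectiveLeaves(s), frontierOracle(h, collapsed))
  }
})

test_that("aggregation conserves per-sample totals and matches brute-force sums", {
  for (seed in 1:10) {
    h <- randomHierarchy(10, seed)
    a <- randomAbundance(h, 5, seed, integer = (seed %% 2 == 0))
    internal <- internalIds(h)
    s <- viewState(h)
    for (id in sample(internal, min(3, length(internal)))) s <- collapseNode(s, id)
    e <- aggregateComposition(a, s)
    raw <- rowSums(abundanceValues(a))
    expect_equal(rowSums(e@values), raw, tolerance = 1e-12)
    labs <- nodeLabels(h)
    for (id in colnames(e@values)) {
      cols <- unname(labs[leavesUnder(h, id)])
      expect_equal(unname(e@values[, id]),
                   unname(rowSums(abundanceValues(a)[, cols, drop = FALSE])),
                   tolerance = 1e-12)
    }
  }
})

test_that("aggregation examples: merged columns sum, identity with no collapse", {
  h <- taxonomyToTree(tinyTaxonomy())
  a <- tinyAbundance()
  e <- aggregateComposition(a, collapseNode(viewState(h), "K1|P1"))
  expect_identical(unname(e@values["s1", ]), c(5, 5))
  e0 <- aggregateComposition(a, viewState(h))
  expect_identical(e0@values[, leafIds(h)], abundanceValues(a)[, leafIds(h)])

  bad <- abundanceTable(abundanceValues(a)[, 1:2])
  expect_error(aggregateComposition(bad, viewState(h)), "does not validate")
})

test_that("paint resolution: nearest painted ancestor wins; errors on bad input", {
  h <- taxonomyToTree(tinyTaxonomy())
  a <- tinyAbundance()
  sRoot <- paintNode(viewState(h), "K1")
  expect_identical(unname(aggregateComposition(a, sRoot)@colorOf), rep(0L, 3))

  s <- paintNode(paintNode(viewState(h), "K1|P1", 2), "O1", 4)
  cof <- aggregateComposition(a, s)@colorOf
  expect_identical(unname(cof[c("O1", "O2", "O3")]), c(4L, 2L, NA_integer_))

  expect_error(paintNode(viewState(h), "O1", 9), "out of range")
  sc <- collapseNode(viewState(h), "K1|P1")
  expect_error(paintNode(sc, "O1"), "hidden inside collapsed subtree 'K1\\|P1'")
})

test_that("color resolution matches the per-leaf nearest-ancestor oracle on random states", {
  for (seed in 1:25) {
    h <- randomHierarchy(sample(4:40, 1L), seed)
    a <- randomAbundance(h, 3, seed)
    s <- viewState(h)
    internal <- internalIds(h)
    for (id in sample(internal, min(2, length(internal)))) s <- collapseNode(s, id)
    paintable <- effectiveLeaves(s)
    paintable <- unique(c(paintable, unlist(lapply(paintable, function(x) pathToRoot(h, x)))))
    for (id in sample(paintable, min(4, length(paintable)))) {
      s <- paintNode(s, id, sample(0:5, 1L))
    }
    e <- aggregateComposition(a, s)
    for (id in names(e@colorOf)) {
      expect_identical(e@colorOf[[id]], colorOracle(s, id))
    }
  }
})

test_that("legend lists active paints in insertion order with node labels", {
  h <- taxonomyToTree(tinyTaxonomy())
  s <- paintNode(paintNode(viewState(h), "K1|P1", 0), "K1|P2", 1)
  lg <- legendEntries(s)
  expect_identical(lg$label, c("P1", "P2"))
  expect_identical(lg$color, c(0L, 1L))
  expect_identical(nrow(legendEntries(viewState(h))), 0L)
})

test_that("repainting a painted node replaces its color in place", {
  h <- taxonomyToTree(tinyTaxonomy())
  s <- paintNode(paintNode(viewState(h), "K1|P1", 0), "K1|P2", 1)
  s <- paintNode(s, "K1|P1", 5)
  lg <- legendEntries(s)
  expect_identical(lg$label, c("P1", "P2"))  # position kept
  expect_identical(lg$color, c(5L, 1L))
})

test_that("view state serializes to JSON and back, including frozen flag", {
  h <- randomHierarchy(15, seed = 9)
  s <- paintNode(viewState(h), internalIds(h)[2], 3)
  s <- collapseNode(s, internalIds(h)[2])
  s <- freezeView(s)
  path <- withr::local_tempfile(fileext = ".json")
  writeViewState(s, path)
  s2 <- readViewState(path, h)
  expect_identical(collapsedNodes(s2), collapsedNodes(s))
  expect_identical(activePaints(s2), activePaints(s))
  expect_identical(s2@suspended, s@suspended)
  expect_identical(s2@palette@queue, s@palette@queue)
  expect_true(s2@frozen)
})
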