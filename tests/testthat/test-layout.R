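test_that("frontier nodes sit at evenly spaced band centers", {
  h <- parseNewick("((A,B),(C,D));")
  cv <- canvasSpec(width = 600, height = 400, margin = 0)
  t <- layoutTree(viewState(h), cv)
  leafY <- t@nodes$y[match(c("A", "B", "C", "D"), t@nodes$id)]
  expect_equal(leafY, c(50, 150, 250, 350))
  expect_true(all(diff(t@nodes$y[match(t@frontier, t@nodes$id)]) > 0))
})

test_that("a fully collapsed tree centers its single frontier node", {
  h <- parseNewick("((A,B),C);")
  s <- collapseNode(viewState(h), rootId(h))
  cv <- canvasSpec(height = 300, margin = 0)
  t <- layoutTree(s, cv)
  expect_identical(t@nodes$id, rootId(h))
  expect_equal(t@nodes$y, 150)
  expect_true(t@nodes$collapsed)
})

test_that("internal y is the mean of children y and x grows with depth", {
  for (seed in 1:10) {
    h <- randomHierarchy(sample(4:50, 1L), seed)
    s <- viewState(h)
    internal <- internalIds(h)
    for (id in sample(internal, min(2, length(internal)))) s <- collapseNode(s, id)
    t <- layoutTree(s)
    nd <- t@nodes
    for (i in seq_len(nrow(nd))) {
      id <- nd$id[i]
      if (nd$frontier[i]) next
      ch <- childrenOf(h, id)
      expect_equal(nd$y[i], mean(nd$y[match(ch, nd$id)]), tolerance = 1e-12)
      expect_identical(nd$depth[i], length(pathToRoot(h, id)) - 1L)
    }
    # only visible nodes are laid out
    expect_setequal(nd$id, unique(c(unlist(lapply(t@frontier, pathToRoot, h = h)))))
  }
})

test_that("normalized bars partition the panel height in frontier order", {
  h <- parseNewick("(A,B,C);")
  v <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("s1", c("A", "B", "C")))
  cv <- canvasSpec(height = 100, margin = 0)
  e <- aggregateComposition(abundanceTable(v), viewState(h))
  b <- layoutBars(e, orderByRows(abundanceTable(v)), cv, normalize = TRUE)
  expect_equal(b@segments$height, c(50, 30, 20))
  expect_equal(b@segments$y, c(0, 50, 80))
  expect_identical(b@segments$leaf, c("A", "B", "C"))
})

test_that("raw mode scales all bars by the largest total", {
  h <- parseNewick("(A,B);")
  v <- rbind(s1 = c(6, 4), s2 = c(3, 2))
  colnames(v) <- c("A", "B")
  a <- abundanceTable(v)
  cv <- canvasSpec(height = 200, margin = 0)
  b <- layoutBars(aggregateComposition(a, viewState(h)), orderByRows(a), cv,
                  normalize = FALSE)
  tot <- tapply(b@segments$height, b@segments$sample, sum)
  expect_equal(as.numeric(tot[c("s1", "s2")]), c(200, 100))  # second bar half height
})

test_that("stacked extents exactly partition the bar and keep zero segments", {
  for (seed in 1:8) {
    h <- randomHierarchy(sample(3:30, 1L), seed)
    a <- randomAbundance(h, 6, seed)
    v <- abundanceValues(a)
    v[v < 6] <- 0  # force zero cells
    v[1, ] <- pmax(v[1, ], 1)  # keep at least one positive row everywhere
    a <- abundanceTable(v)
    s <- viewState(h)
    e <- aggregateComposition(a, s)
    cv <- canvasSpec()
    b <- layoutBars(e, orderByRows(a), cv, normalize = TRUE)
    innerH <- cv@height - 2 * cv@margin
    for (sm in sampleIds(a)) {
      seg <- b@segments[b@segments$sample == sm, ]
      expect_identical(seg$leaf, colnames(e@values))  # zero segments retained
      if (sum(e@values[sm, ]) > 0) {
        expect_equal(sum(seg$height), innerH, tolerance = 1e-6 * innerH)
        expect_equal(seg$y[1], cv@margin)
        expect_equal(seg$y[-1], head(seg$y + seg$height, -1), tolerance = 1e-9)
      }
    }
  }
})

test_that("tree leaf order and bar stacking order agree (panel linkage)", {
  h <- randomHierarchy(12, seed = 5)
  a <- randomAbundance(h, 3, seed = 5)
  s <- collapseNode(viewState(h), internalIds(h)[2])
  e <- aggregateComposition(a, s)
  t <- layoutTree(s)
  b <- layoutBars(e, orderByRows(a))
  expect_identical(t@frontier, b@frontier)
  yy <- t@nodes$y[match(t@frontier, t@nodes$id)]
  seg1 <- b@segments[b@segments$sample == sampleIds(a)[1], ]
  expect_identical(seg1$leaf[order(seg1$y)], t@frontier[order(yy)])
})

test_that("layoutBars rejects samples missing from the composition", {
  h <- parseNewick("(A,B);")
  v <- rbind(s1 = c(1, 2))
  colnames(v) <- c("A", "B")
  a <- abundanceTable(v)
  e <- aggregateComposition(a, viewState(h))
  ghost <- new("Arrangement", orderedSamples = c("s1", "sX"),
               groups = character(0), representatives = character(0))
  expect_error(layoutBars(e, ghost), "sX")
})

test_that("hover map answers identity and single-node queries", {
  h <- parseNewick("((A,B),C);")
  t <- layoutTree(viewState(h))
  m <- hoverMap(t)
  for (i in seq_len(nrow(t@nodes))) {
    expect_identical(queryHover(m, t@nodes$x[i], t@nodes$y[i]), t@nodes$id[i])
  }
  s1 <- collapseNode(viewState(h), rootId(h))
  m1 <- hoverMap(layoutTree(s1))
  set.seed(1)
  expect_identical(unique(queryHover(m1, runif(20, 0, 800), runif(20, 0, 500))),
                   rootId(h))
})

test_that("hover map matches brute-force nearest-site search with pre-order ties", {
  set.seed(99)
  h <- randomHierarchy(40, seed = 99)  # ~50+ visible nodes
  t <- layoutTree(viewState(h))
  m <- hoverMap(t)
  qx <- runif(500, 0, 800)
  qy <- runif(500, 0, 500)
  got <- queryHover(m, qx, qy)
  for (k in seq_along(qx)) {
    want <- t@nodes$id[nearestSiteOracle(m@sites, m@preorder, c(qx[k], qy[k]))]
    expect_identical(got[k], want)
  }
  # exact ties between coincident x or y bands resolve to smaller pre-order
  sites <- rbind(c(0, 0), c(10, 0))
  tl <- t; tl@nodes <- t@nodes[1:2, ]; tl@nodes$x <- sites[, 1]; tl@nodes$y <- sites[, 2]
  mm <- hoverMap(tl)
  expect_identical(queryHover(mm, 5, 3), tl@nodes$id[which.min(tl@nodes$preorder[1:2])])
})

test_that("layouts are bit-identical across repeated runs", {
  h <- randomHierarchy(25, seed = 8)
  a <- randomAbundance(h, 5, seed = 8)
  s <- paintNode(collapseNode(viewState(h), internalIds(h)[3]), rootId(h), 1)
  t1 <- layoutTree(s); t2 <- layoutTree(s)
  expect_identical(t1@nodes, t2@nodes)
  expect_identical(t1@edges, t2@edges)
  e <- aggregateComposition(a, s)
  b1 <- layoutBars(e, orderByRows(a)); b2 <- layoutBars(e, orderByRows(a))
  expect_identical(b1@segments, b2@segments)
})

test_that("layout JSON serialization is parseable and complete", {
  h <- parseNewick("((A,B),C);")
  a <- abundanceTable(matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
  s <- paintNode(viewState(h), rootId(h))
  e <- aggregateComposition(a, s)
  t <- layoutTree(s); b <- layoutBars(e, orderByRows(a))
  obj <- jsonlite::fromJSON(layoutToJson(t, b, legendEntries(s)))
  expect_setequal(names(obj), c("canvas", "tree", "bars", "legend"))
  expect_identical(obj$tree$frontier, c("A", "B", "C"))
})
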