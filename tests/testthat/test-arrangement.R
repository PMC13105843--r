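sampleMatrix <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, sprintf("t%d", seq_len(ncol(m))))
  abundanceTable(m)
}

test_that("orderByRows keeps input order verbatim", {
  v <- matrix(1, 3, 2, dimnames = list(c("s3", "s1", "s2"), c("A", "B")))
  expect_identical(orderedSamples(orderByRows(abundanceTable(v))), c("s3", "s1", "s2"))
  expect_identical(orderedSamples(orderByRows(abundanceTable(v[1, , drop = FALSE]))), "s3")
})

test_that("Bray-Curtis unit values: identity, disjoint support, hand-computed case", {
  v <- rbind(x = c(2, 1, 0), y = c(1, 1, 1), z = c(2, 1, 0))
  colnames(v) <- c("A", "B", "C")
  d <- as.matrix(brayCurtis(abundanceTable(v)))
  expect_equal(d["x", "z"], 0, tolerance = 1e-12)
  expect_equal(d["x", "y"], 1 / 3, tolerance = 1e-12)

  disj <- rbind(x = c(1, 0), y = c(0, 1))
  colnames(disj) <- c("A", "B")
  expect_equal(as.matrix(brayCurtis(abundanceTable(disj)))["x", "y"], 1, tolerance = 1e-12)
})

test_that("Bray-Curtis is symmetric, zero-diagonal, bounded, and matches the formula", {
  set.seed(11)
  v <- matrix(rpois(8 * 6, 5), 8, 6,
              dimnames = list(sprintf("s%d", 1:8), sprintf("t%d", 1:6)))
  d <- as.matrix(brayCurtis(abundanceTable(v)))
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_identical(unname(diag(d)), rep(0, 8))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(d[i, j], bcOracle(v[i, ], v[j, ]), tolerance = 1e-12)
  }

  zeros <- matrix(0, 2, 3, dimnames = list(c("z1", "z2"), c("A", "B", "C")))
  expect_error(brayCurtis(abundanceTable(zeros)), "z1, z2")
})

test_that("clustering order puts duplicates adjacent and is a deterministic permutation", {
  a <- sampleMatrix(list(c(1, 0), c(0, 10), c(1, 0)), c("s1", "s2", "s3"))
  ord <- orderedSamples(orderByClustering(a))
  expect_setequal(ord, c("s1", "s2", "s3"))
  expect_equal(abs(diff(match(c("s1", "s3"), ord))), 1)  # zero-distance pair adjacent

  two <- sampleMatrix(list(c(1, 1), c(1, 1)), c("s1", "s2"))
  expect_identical(orderedSamples(orderByClustering(two)), c("s1", "s2"))

  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(sprintf("s%02d", 1:12), sprintf("t%d", 1:5)))
    a <- abundanceTable(abs(v))
    o1 <- orderedSamples(orderByClustering(a))
    o2 <- orderedSamples(orderByClustering(a))
    expect_identical(o1, o2)
    expect_setequal(o1, sprintf("s%02d", 1:12))
  }
})

test_that("fewer than two samples falls back to input order with a warning", {
  one <- sampleMatrix(list(c(1, 2)), "only")
  expect_warning(arr <- orderByClustering(one), "fewer than 2")
  expect_identical(orderedSamples(arr), "only")
})

test_that("agglomeration induces the same partitions as hclust on tie-free data", {
  # cross-check against the reference implementation where tie-breaks are moot
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(sprintf("s%d", 1:10), sprintf("t%d", 1:4)))
    D <- as.matrix(dist(v))
    hc <- hclust(as.dist(D), method = "complete")
    for (k in c(2, 4, 7)) {
      res <- treestack:::.agglomerate(D, "complete", snapK = k)
      mine <- integer(10)
      for (ci in seq_along(res$clusters)) mine[res$clusters[[ci]]] <- ci
      ref <- cutree(hc, k)
      # same partition up to relabeling: each of my clusters hits one ref label
      expect_true(all(rowSums(table(mine, ref) > 0) == 1))
      expect_true(all(colSums(table(mine, ref) > 0) == 1))
    }
  }
})

test_that("grouped ordering keeps groups contiguous and clusters within groups", {
  set.seed(2)
  v <- matrix(rpois(5 * 4, 6), 5, 4,
              dimnames = list(c("c1", "c2", "c3", "h1", "h2"), sprintf("t%d", 1:4)))
  v["c3", ] <- v["c1", ]  # duplicate pair within control
  a <- abundanceTable(v)
  groups <- stats::setNames(c("control", "control", "control", "hfhs", "hfhs"),
                            rownames(v))
  arr <- orderGrouped(a, groups)
  ord <- orderedSamples(arr)
  expect_identical(sort(match(c("c1", "c2", "c3"), ord)), 1:3)  # controls first
  expect_equal(abs(diff(match(c("c1", "c3"), ord))), 1)         # duplicates adjacent
  expect_identical(unname(sampleGroups(arr)[ord[4:5]]), c("hfhs", "hfhs"))

  # one group only degenerates to plain clustering order
  g1 <- stats::setNames(rep("g", 5), rownames(v))
  expect_identical(orderedSamples(orderGrouped(a, g1)),
                   orderedSamples(orderByClustering(a)))

  # single-sample groups come out in supplied group order
  tiny <- sampleMatrix(list(c(1, 0), c(0, 1)), c("x", "y"))
  gt <- stats::setNames(c("B", "A"), c("x", "y"))
  expect_identical(orderedSamples(orderGrouped(tiny, gt)), c("x", "y"))
  expect_identical(orderedSamples(orderGrouped(tiny, gt, groupOrder = c("A", "B"))),
                   c("y", "x"))

  expect_error(orderGrouped(a, groups[1:4]), "without a group")
})

test_that("representative selection: duplicate pairs, k = n, bounds", {
  v <- rbind(a1 = c(5, 0, 0), a2 = c(5, 0, 0), b1 = c(0, 7, 1), b2 = c(0, 7, 1))
  colnames(v) <- c("t1", "t2", "t3")
  a <- abundanceTable(v)
  arr <- selectRepresentatives(a, 2)
  reps <- orderedSamples(arr)
  expect_length(reps, 2L)
  expect_true(any(c("a1", "a2") %in% reps) && any(c("b1", "b2") %in% reps))
  expect_identical(reps, c("a1", "b1"))  # smallest-index tie-break

  expect_setequal(orderedSamples(selectRepresentatives(a, 4)), rownames(v))
  expect_error(selectRepresentatives(a, 5), "k must lie")
  expect_length(orderedSamples(selectRepresentatives(a, 1)), 1L)
})

test_that("bc-medoid representatives equal exhaustive per-cluster medoid search", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rpois(8 * 5, 7), 8, 5,
                dimnames = list(sprintf("s%d", 1:8), sprintf("t%d", 1:5)))
    a <- abundanceTable(v)
    D <- as.matrix(brayCurtis(a))
    k <- 3L
    arr <- selectRepresentatives(a, k, method = "bc-medoid")
    res <- treestack:::.agglomerate(D, "complete", snapK = k)
    expected <- vapply(res$clusters, function(m) rownames(v)[medoidOracle(D, m)],
                       character(1))
    expect_identical(unname(representatives(arr)), expected)
    # every representative belongs to its own cluster
    for (ci in seq_len(k)) {
      expect_true(match(representatives(arr)[[ci]], rownames(v)) %in% res$clusters[[ci]])
    }
  }
})

test_that("centroid representatives are the members nearest the cluster mean", {
  set.seed(4)
  v <- matrix(rnorm(9 * 3, 10), 9, 3,
              dimnames = list(sprintf("s%d", 1:9), sprintf("t%d", 1:3)))
  a <- abundanceTable(abs(v))
  k <- 3L
  arr <- selectRepresentatives(a, k, method = "centroid")
  D <- as.matrix(dist(abundanceValues(a)))
  res <- treestack:::.agglomerate(D, "complete", snapK = k)
  for (ci in seq_len(k)) {
    m <- sort(res$clusters[[ci]])
    ctr <- colMeans(abundanceValues(a)[m, , drop = FALSE])
    dd <- apply(abundanceValues(a)[m, , drop = FALSE], 1, function(r) sqrt(sum((r - ctr)^2)))
    expect_identical(representatives(arr)[[ci]], rownames(v)[m[which.min(dd)]])
  }
})
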