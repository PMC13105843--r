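# Fixture builders and brute-force oracles shared across test files.
# Oracles deliberately avoid the code paths they check: they use only the
# public accessors (parentOf, leafIds, activePaints, ...) and naive scans.

randomNewick <- function(labels) {
  build <- function(lab) {
    if (length(lab) == 1L) return(lab)
    k <- if (length(lab) == 2L) 2L else sample(2:min(4L, length(lab)), 1L)
    grp <- sort(sample(rep(seq_len(k), length.out = length(lab))))
    parts <- vapply(split(lab, grp), build, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(labels), ";")
}

randomHierarchy <- function(nLeaves, seed) {
  set.seed(seed)
  parseNewick(randomNewick(paste0("t", seq_len(nLeaves))))
}

internalIds <- function(h) setdiff(nodeIds(h), leafIds(h))

randomAbundance <- function(h, nSamples, seed, integer = TRUE) {
  set.seed(seed)
  p <- length(leafIds(h))
  v <- if (integer) {
    matrix(rpois(nSamples * p, lambda = 8), nrow = nSamples)
  } else {
    matrix(rexp(nSamples * p, rate = 0.2), nrow = nSamples)
  }
  dimnames(v) <- list(sprintf("s%02d", seq_len(nSamples)),
                      unname(nodeLabels(h)[leafIds(h)]))
  abundanceTable(v)
}

# root -> node label path via parent pointers only
pathToRoot <- function(h, id) {
  out <- id
  p <- parentOf(h, id)
  while (!is.na(p)) {
    out <- c(p, out)
    p <- parentOf(h, p)
  }
  out
}

# per-leaf ancestor scan: each leaf is represented by its topmost collapsed
# ancestor (if any), and representatives are deduplicated in leaf order
frontierOracle <- function(h, collapsed) {
  reps <- vapply(leafIds(h), function(leaf) {
    path <- pathToRoot(h, leaf)
    hit <- path[path %in% collapsed]
    if (length(hit)) hit[1L] else leaf
  }, character(1))
  unique(unname(reps))
}

# nearest painted visible ancestor (including the node itself), brute force
colorOracle <- function(s, id) {
  h <- s@hierarchy
  paints <- activePaints(s)
  chain <- rev(pathToRoot(h, id))  # node first, root last
  for (nd in chain) {
    i <- match(nd, paints$node)
    if (!is.na(i)) return(paints$color[i])
  }
  NA_integer_
}

bcOracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# exhaustive medoid: cluster member minimizing summed dissimilarity (smallest
# index on ties)
medoidOracle <- function(D, members) {
  members <- sort(members)
  scores <- vapply(members, function(i) sum(D[i, members]), numeric(1))
  members[which.min(scores)]
}

nearestSiteOracle <- function(sites, preorder, q) {
  d2 <- (sites[, 1L] - q[1L])^2 + (sites[, 2L] - q[2L])^2
  cand <- which(d2 == min(d2))
  cand[which.min(preorder[cand])]
}

tinyTaxonomy <- function() {
  data.frame(Kingdom = "K1", Phylum = c("P1", "P1", "P2"),
             Order = c("O1", "O2", "O3"), stringsAsFactors = FALSE)
}

tinyAbundance <- function() {
  abundanceTable(matrix(c(2, 3, 5,
                          1, 1, 1), nrow = 2, byrow = TRUE,
                        dimnames = list(c("s1", "s2"), c("O1", "O2", "O3"))))
}
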