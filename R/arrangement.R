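#' @include AllClasses.R AllGenerics.R abundance.R
NULL

#' @describeIn Arrangement-class sample ids in display order.
#' @export
setMethod("orderedSamples", "Arrangement", function(x) x@orderedSamples)

#' @describeIn Arrangement-class sample -> group mapping (length 0 if
#'   ungrouped).
#' @export
setMethod("sampleGroups", "Arrangement", function(x) x@groups)

#' @describeIn Arrangement-class cluster index -> representative sample
#'   (length 0 unless representative selection was used).
#' @export
setMethod("representatives", "Arrangement", function(x) x@representatives)

setMethod("show", "Arrangement", function(object) {
  cat(sprintf("Arrangement: %d samples%s%s\n", length(object@orderedSamples),
              if (length(object@groups)) sprintf(", %d group(s)", length(unique(object@groups))) else "",
              if (length(object@representatives)) sprintf(", %d representative(s)", length(object@representatives)) else ""))
})

#' @export
#' @describeIn DissimilarityMatrix-class the symmetric matrix.
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@values)

setMethod("show", "DissimilarityMatrix", function(object) {
  cat(sprintf("DissimilarityMatrix (%s): %d samples\n", object@metric, nrow(object@values)))
})

#' Order samples by their input row order
#'
#' Keeps the abundance matrix's row order verbatim, so pre-sorted inputs
#' (time, experimental group, any study factor) pass straight through.
#'
#' @param a an [AbundanceTable-class].
#' @return an [Arrangement-class].
#' @export
orderByRows <- function(a) {
  stopifnot(is(a, "AbundanceTable"))
  new("Arrangement", orderedSamples = sampleIds(a),
      groups = character(0), representatives = character(0))
}

#' Bray-Curtis dissimilarities between samples
#'
#' `BC(x, y) = sum |x_k - y_k| / sum (x_k + y_k)`: 0 for identical samples, 1
#' for disjoint support, bounded in `[0, 1]` for non-negative input. It is not
#' a metric (the triangle inequality can fail). A pair of all-zero samples has
#' no defined dissimilarity and is an error.
#'
#' @param a an [AbundanceTable-class] with non-negative values.
#' @return a [DissimilarityMatrix-class] tagged `"bray-curtis"`.
#' @export
brayCurtis <- function(a) {
  stopifnot(is(a, "AbundanceTable"))
  v <- abundanceValues(a)
  if (any(v < 0)) stop("Bray-Curtis requires non-negative values", call. = FALSE)
  zero <- rownames(v)[rowSums(v) == 0]
  if (length(zero) >= 2L) {
    stop(sprintf("Bray-Curtis undefined for all-zero sample pairs: %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(vegan::vegdist(v, method = "bray"))
  diag(m) <- 0
  dimnames(m) <- list(rownames(v), rownames(v))
  new("DissimilarityMatrix", values = m, metric = "bray-curtis")
}

.euclidean <- function(a) {
  v <- abundanceValues(a)
  m <- as.matrix(stats::dist(v, method = "euclidean"))
  dimnames(m) <- list(rownames(v), rownames(v))
  new("DissimilarityMatrix", values = m, metric = "euclidean")
}

.distFor <- function(a, metric) {
  switch(metric,
         "euclidean" = .euclidean(a),
         "bray-curtis" = brayCurtis(a),
         stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

# Deterministic agglomerative clustering. Among equal-distance merges, the
# pair with the lexicographically smallest (smallest-original-index-per-
# cluster) key merges first; dendrogram child order puts the cluster holding
# the smaller original index first. Returns the dendrogram leaf order of the
# original indices, and the cluster membership when `snapK` clusters remain.
.agglomerate <- function(D, linkage = "complete", snapK = 1L) {
  n <- nrow(D)
  members <- lapply(seq_len(n), function(i) i)
  reps <- seq_len(n)
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  d <- D
  diag(d) <- Inf
  snapshot <- NULL
  takeSnap <- function() {
    idx <- which(active)
    members[idx[order(reps[idx])]]
  }
  if (snapK == n) snapshot <- takeSnap()
  while (sum(active) > 1L) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    dmin <- min(dm)
    cand <- which(dm == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keyA <- pmin(reps[cand[, 1L]], reps[cand[, 2L]])
    keyB <- pmax(reps[cand[, 1L]], reps[cand[, 2L]])
    pick <- order(keyA, keyB)[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    if (reps[j] < reps[i]) { tmp <- i; i <- j; j <- tmp }
    # merge j into i; i's members (smaller original index) come first
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    newd <- switch(linkage,
      complete = pmax(d[i, others], d[j, others]),
      single = pmin(d[i, others], d[j, others]),
      average = (sizes[i] * d[i, others] + sizes[j] * d[j, others]) / (sizes[i] + sizes[j]),
      stop(sprintf("unknown linkage '%s'", linkage), call. = FALSE))
    d[i, others] <- newd
    d[others, i] <- newd
    members[[i]] <- c(members[[i]], members[[j]])
    reps[i] <- min(reps[i], reps[j])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    if (sum(active) == snapK) snapshot <- takeSnap()
  }
  ord <- members[[which(active)]]
  if (!is.null(snapshot)) {
    # order clusters by their first member's position in the final leaf order
    pos <- vapply(snapshot, function(m) min(match(m, ord)), numeric(1))
    snapshot <- snapshot[order(pos)]
  }
  list(order = ord, clusters = snapshot)
}

#' Order samples by hierarchical clustering
#'
#' Agglomerative clustering (default: complete linkage on Euclidean
#' distances, the recipe used for treatment-group ordering in diet-intervention
#' microbiome barplots); samples are returned in the dendrogram's leaf order.
#' Tie-breaks are deterministic: among equal-distance merges the pair with
#' the smallest original indices merges first, and the cluster holding the
#' smaller original index becomes the left child, so duplicate samples end up
#' adjacent and runs are reproducible.
#'
#' @param a an [AbundanceTable-class] with at least 2 samples (fewer: input
#'   order with a warning).
#' @param metric `"euclidean"` (default) or `"bray-curtis"`.
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @return an [Arrangement-class].
#' @export
orderByClustering <- function(a, metric = "euclidean", linkage = "complete") {
  stopifnot(is(a, "AbundanceTable"))
  ids <- sampleIds(a)
  if (length(ids) < 2L) {
    warning("fewer than 2 samples; returning input order")
    return(orderByRows(a))
  }
  D <- as.matrix(.distFor(a, metric))
  res <- .agglomerate(D, linkage = linkage)
  new("Arrangement", orderedSamples = ids[res$order],
      groups = character(0), representatives = character(0))
}

#' Grouped sample ordering
#'
#' Lays the groups out contiguously in display order and orders the samples
#' within each group independently by [orderByClustering()] — e.g. all
#' control samples on the left and all treatment samples on the right, each
#' side clustered by community similarity.
#'
#' @param a an [AbundanceTable-class].
#' @param groups named character vector sample -> group label; every sample of
#'   `a` must be present. A `groupOrder` attribute (as set by
#'   [readSampleMetadata()]) or the `groupOrder` argument fixes the group
#'   display order; default is first appearance among the samples.
#' @param metric,linkage passed to [orderByClustering()].
#' @param groupOrder optional explicit group order.
#' @return an [Arrangement-class] with the `groups` slot filled.
#' @export
orderGrouped <- function(a, groups, metric = "euclidean", linkage = "complete",
                         groupOrder = NULL) {
  stopifnot(is(a, "AbundanceTable"))
  ids <- sampleIds(a)
  missing <- setdiff(ids, names(groups))
  if (length(missing)) {
    stop(sprintf("samples without a group label: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  groups <- groups[ids]
  ord <- groupOrder %||% attr(groups, "groupOrder") %||% unique(unname(groups))
  unknown <- setdiff(unname(groups), ord)
  if (length(unknown)) {
    stop(sprintf("groupOrder omits group(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  v <- abundanceValues(a)
  ordered <- character(0)
  for (g in ord) {
    gi <- ids[unname(groups) == g]
    if (!length(gi)) next
    sub <- abundanceTable(v[gi, , drop = FALSE])
    arr <- if (length(gi) < 2L) orderByRows(sub) else orderByClustering(sub, metric, linkage)
    ordered <- c(ordered, orderedSamples(arr))
  }
  new("Arrangement", orderedSamples = ordered,
      groups = stats::setNames(unname(groups), ids), representatives = character(0))
}

#' Select one representative sample per cluster
#'
#' Cuts the complete-linkage dendrogram into `k` clusters and keeps one
#' member per cluster, so very large sample collections can be drawn as `k`
#' bars. `"centroid"` clusters on Euclidean distances and keeps the member
#' closest (Euclidean) to the cluster mean; `"bc-medoid"` clusters on
#' Bray-Curtis dissimilarities and keeps the member minimizing the summed
#' dissimilarity to its cluster (the medoid). Ties go to the smallest sample
#' index. No internal normalization is applied: centroids live on the scale
#' of the input values.
#'
#' @param a an [AbundanceTable-class].
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param method `"centroid"` (default) or `"bc-medoid"`.
#' @return an [Arrangement-class] whose `orderedSamples` are the `k`
#'   representatives in dendrogram cluster order and whose `representatives`
#'   slot maps cluster index to sample id.
#' @export
selectRepresentatives <- function(a, k, method = c("centroid", "bc-medoid")) {
  stopifnot(is(a, "AbundanceTable"))
  method <- match.arg(method)
  ids <- sampleIds(a)
  n <- length(ids)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop(sprintf("k must lie in [1, %d], got %d", n, k), call. = FALSE)
  }
  metric <- if (method == "centroid") "euclidean" else "bray-curtis"
  D <- as.matrix(.distFor(a, metric))
  res <- .agglomerate(D, linkage = "complete", snapK = k)
  v <- abundanceValues(a)
  reps <- vapply(res$clusters, function(m) {
    m <- sort(m)
    if (length(m) == 1L) return(m)
    score <- if (method == "centroid") {
      ctr <- colMeans(v[m, , drop = FALSE])
      vapply(m, function(i) sqrt(sum((v[i, ] - ctr)^2)), numeric(1))
    } else {
      vapply(m, function(i) sum(D[i, m]), numeric(1))
    }
    m[which.min(score)]  # which.min takes the first minimum: smallest index wins
  }, numeric(1))
  new("Arrangement", orderedSamples = ids[reps], groups = character(0),
      representatives = stats::setNames(ids[reps], as.character(seq_along(reps))))
}
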