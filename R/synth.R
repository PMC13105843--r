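#' @include AllClasses.R hierarchy.R abundance.R
NULL

#' Construct a synthetic community specification
#'
#' Defaults emulate a small two-arm intervention study: 20 samples per group
#' over a 30-leaf taxonomy with four internal ranks, log-normal counts with
#' unit log-scale noise and 10% zero inflation, and (optionally) a planted
#' multiplicative fold change on one subtree in the treatment group — the
#' structure of a diet-intervention gut-microbiome contrast, where one clade
#' rises under treatment while the rest is unchanged.
#'
#' @param nPerGroup samples per group (default 20).
#' @param nLeaves number of leaves (default 30).
#' @param ranks internal rank names, coarse to fine (default Kingdom, Phylum,
#'   Class, Order; leaves are OTUs below the finest rank).
#' @param targetNode id of the subtree carrying the fold (default `""`: the
#'   first second-rank node of the generated tree).
#' @param fold multiplicative group effect on the target subtree (default 1,
#'   i.e. both groups are draws from identical distributions).
#' @param location mean of the per-leaf log-mean abundances (default 2).
#' @param scale log-normal noise sd (default 1; 0 switches noise off).
#' @param zeroProb zero-inflation probability per cell (default 0.1).
#' @param seed RNG seed, mandatory.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nPerGroup = 20L, nLeaves = 30L,
                          ranks = c("Kingdom", "Phylum", "Class", "Order"),
                          targetNode = "", fold = 1, location = 2, scale = 1,
                          zeroProb = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  new("SyntheticSpec", nPerGroup = as.integer(nPerGroup),
      nLeaves = as.integer(nLeaves), ranks = ranks, targetNode = targetNode,
      fold = fold, location = location, scale = scale, zeroProb = zeroProb,
      seed = as.integer(seed))
}

# random taxonomy table: one node at the coarsest rank, geometric growth of
# internal nodes below it, every internal node guaranteed at least one child
.synthTaxonomy <- function(nLeaves, ranks) {
  R <- length(ranks)
  counts <- pmax(1L, pmin(nLeaves, as.integer(round(nLeaves^((seq_len(R) - 1) / R)))))
  prefix <- toupper(substr(ranks, 1L, 1L))
  prefix[1L] <- "K"
  names <- lapply(seq_len(R), function(r) sprintf("%s%d", prefix[r], seq_len(counts[r])))
  parentOf <- vector("list", R)
  for (r in 2:R) {
    np <- counts[r - 1L]
    n <- counts[r]
    # first np children round-robin (coverage), remainder uniform
    assign <- c(seq_len(min(np, n)), if (n > np) sample.int(np, n - np, replace = TRUE))
    parentOf[[r]] <- assign
  }
  nf <- counts[R]
  leafParent <- c(seq_len(min(nf, nLeaves)),
                  if (nLeaves > nf) sample.int(nf, nLeaves - nf, replace = TRUE))
  lineage <- function(r, i) {  # names along the path down to rank r, node i
    if (r == 1L) return(names[[1L]][i])
    c(lineage(r - 1L, parentOf[[r]][i]), names[[r]][i])
  }
  rows <- lapply(seq_len(nLeaves), function(j) {
    c(lineage(R, leafParent[j]), sprintf("OTU_%d", j))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(tab) <- c(ranks, "OTU")
  tab
}

#' Generate a synthetic taxonomy + abundance fixture
#'
#' Reproducible given the spec's seed (the global RNG state is saved and
#' restored). Counts are rounded log-normal draws (not multinomial), so raw-
#' mode bars have unequal totals. The treatment group's draws on the target
#' subtree are control-model draws scaled by the fold before rounding, so in
#' the noise-free limit the treatment mean on the target leaves is exactly
#' `fold` times the control mean.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `taxonomy` (rank table), `hierarchy`
#'   ([Hierarchy-class]), `abundance` ([AbundanceTable-class], groups
#'   stacked control then treatment), `metadata` (data.frame `sample`,
#'   `group`), `targetNode` (resolved id) and `targetLeaves`.
#' @export
synthCommunity <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec@seed)

  tab <- .synthTaxonomy(spec@nLeaves, spec@ranks)
  h <- taxonomyToTree(tab)
  target <- spec@targetNode
  if (!nzchar(target)) {
    # first node of the second rank (first child of the root)
    target <- childrenOf(h, rootId(h))[1L]
  }
  if (!target %in% nodeIds(h)) {
    stop(sprintf("target node '%s' absent from the generated tree", target), call. = FALSE)
  }
  targetLeaves <- leavesUnder(h, target)

  n <- spec@nPerGroup
  leaves <- leafIds(h)  # leaf ids equal the OTU labels
  p <- length(leaves)
  meanlog <- stats::rnorm(p, spec@location, 1)
  draw <- function() {
    matrix(stats::rlnorm(n * p, meanlog = rep(meanlog, each = n), sdlog = spec@scale),
           nrow = n, ncol = p)
  }
  ctrl <- draw()
  trt <- draw()
  tcol <- match(targetLeaves, leaves)
  trt[, tcol] <- trt[, tcol] * spec@fold
  vals <- rbind(ctrl, trt)
  if (spec@zeroProb > 0) {
    mask <- matrix(stats::runif(length(vals)) < spec@zeroProb, nrow = nrow(vals))
    vals[mask] <- 0
  }
  vals <- round(vals)
  rownames(vals) <- c(sprintf("ctrl_%02d", seq_len(n)), sprintf("trt_%02d", seq_len(n)))
  colnames(vals) <- leaves
  meta <- data.frame(sample = rownames(vals),
                     group = rep(c("control", "treatment"), each = n),
                     stringsAsFactors = FALSE)
  list(taxonomy = tab, hierarchy = h, abundance = abundanceTable(vals),
       metadata = meta, targetNode = target, targetLeaves = targetLeaves)
}

#' Write a synthetic fixture to delimited files
#'
#' Dumps `abundance.tsv`, `taxonomy.tsv` and `metadata.tsv` (plus
#' `tree.nwk`) into a directory, in the formats the readers and the CLI
#' accept.
#'
#' @param fx list from [synthCommunity()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
writeFixtures <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- abundanceValues(fx$abundance)
  ab <- data.frame(sample = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(writeNewick(fx$hierarchy), file.path(dir, "tree.nwk"))
  invisible(dir)
}
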