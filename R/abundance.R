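#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an abundance table
#'
#' @param values numeric matrix or data.frame, samples in rows and taxa in
#'   columns, with sample ids as rownames and taxon ids as colnames.
#' @return an [AbundanceTable-class].
#' @export
abundanceTable <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("AbundanceTable", values = values)
}

#' @describeIn AbundanceTable-class sample ids (row order).
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) rownames(x@values))

#' @describeIn AbundanceTable-class taxon ids (column order).
#' @export
setMethod("taxonIds", "AbundanceTable", function(x) colnames(x@values))

#' @describeIn AbundanceTable-class the numeric matrix.
#' @export
setMethod("abundanceValues", "AbundanceTable", function(x) x@values)

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d samples x %d taxa; totals %s\n",
              nrow(object@values), ncol(object@values),
              paste(format(range(rowSums(object@values)), digits = 4), collapse = " - ")))
})

#' Read an abundance matrix from delimited text
#'
#' First column holds sample ids, header row holds taxon ids.
#'
#' @param path file path.
#' @param sep field separator (`"\t"` default; use `","` for CSV).
#' @return an [AbundanceTable-class].
#' @export
readAbundance <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE)
  abundanceTable(as.matrix(df))
}

#' Read a taxonomy rank table from delimited text
#'
#' Header row = rank names, coarse to fine. If the first column is a taxon id
#' rather than a rank, set `idColumn = TRUE` to drop it.
#'
#' @param path file path.
#' @param sep field separator.
#' @param idColumn is the first column a taxon identifier column?
#' @return a character data.frame suitable for [taxonomyToTree()].
#' @export
readTaxonomy <- function(path, sep = "\t", idColumn = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (idColumn) df <- df[, -1L, drop = FALSE]
  df
}

#' Read sample metadata (sample id, group label)
#'
#' Two-column delimited file mapping sample ids to group labels. Group display
#' order is first-appearance order unless `groupOrder` is given.
#'
#' @param path file path.
#' @param sep field separator.
#' @param groupOrder optional explicit group display order.
#' @return named character vector sample -> group, with a `groupOrder`
#'   attribute.
#' @export
readSampleMetadata <- function(path, sep = "\t", groupOrder = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("metadata needs two columns: sample id, group", call. = FALSE)
  groups <- stats::setNames(df[[2L]], df[[1L]])
  ord <- if (is.null(groupOrder)) unique(unname(groups)) else groupOrder
  missing <- setdiff(unname(groups), ord)
  if (length(missing)) {
    stop(sprintf("groupOrder omits group(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  attr(groups, "groupOrder") <- ord
  groups
}
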