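#' @include AllClasses.R
NULL

#' @rdname hierarchy-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("childrenOf", function(x, id) standardGeneric("childrenOf"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("parentOf", function(x, id) standardGeneric("parentOf"))
#' @rdname hierarchy-accessors
#' @export
setGeneric("isLeaf", function(x, id) standardGeneric("isLeaf"))

#' @rdname leavesUnder
#' @export
setGeneric("leavesUnder", function(x, id) standardGeneric("leavesUnder"))

#' @rdname searchLabels
#' @export
setGeneric("searchLabels", function(x, query) standardGeneric("searchLabels"))

#' @rdname abundance-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname abundance-accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))
#' @rdname abundance-accessors
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname viewstate-accessors
#' @export
setGeneric("collapsedNodes", function(x) standardGeneric("collapsedNodes"))
#' @rdname viewstate-accessors
#' @export
setGeneric("activePaints", function(x) standardGeneric("activePaints"))
#' @rdname viewstate-accessors
#' @export
setGeneric("paletteColors", function(x) standardGeneric("paletteColors"))

#' @rdname arrangement-accessors
#' @export
setGeneric("orderedSamples", function(x) standardGeneric("orderedSamples"))
#' @rdname arrangement-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname arrangement-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
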