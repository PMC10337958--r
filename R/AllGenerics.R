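#' @rdname AbundanceTable-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("isRelative", function(x) standardGeneric("isRelative"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setGeneric("edgeShortfall", function(x) standardGeneric("edgeShortfall"))

#' @rdname NetworkComparison-accessors
#' @export
setGeneric("jaccard", function(x) standardGeneric("jaccard"))

#' @rdname NetworkComparison-accessors
#' @export
setGeneric("nullJaccards", function(x) standardGeneric("nullJaccards"))

#' @rdname NetworkComparison-accessors
#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))

#' @rdname ImpactProfile-accessors
#' @export
setGeneric("impactScores", function(x) standardGeneric("impactScores"))
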