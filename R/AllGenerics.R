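#' @import methods
NULL

#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @export
setGeneric("hillCoefficient", function(object) standardGeneric("hillCoefficient"))

#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))

#' @export
setGeneric("kdLowerBound", function(object) standardGeneric("kdLowerBound"))

#' @export
setGeneric("fitRSS", function(object) standardGeneric("fitRSS"))

#' @export
setGeneric("slotFrequencies", function(object) standardGeneric("slotFrequencies"))

#' @export
setGeneric("monoFrequencies", function(object) standardGeneric("monoFrequencies"))

#' @export
setGeneric("nSequences", function(object) standardGeneric("nSequences"))

#' @export
setGeneric("fisherP", function(object) standardGeneric("fisherP"))

#' @export
setGeneric("contingencyTable", function(object) standardGeneric("contingencyTable"))

#' @export
setGeneric("trendTest", function(object) standardGeneric("trendTest"))
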