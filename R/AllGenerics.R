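#' @rdname GenotypeCalls
#' @param x a `GenotypeCalls` object.
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))

#' @rdname GenotypeCalls
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeCalls
#' @export
setGeneric("alleleCalls", function(x) standardGeneric("alleleCalls"))

#' @rdname GenotypeCalls
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname GenotypeCalls
#' @export
setGeneric("genoQual", function(x) standardGeneric("genoQual"))

#' @rdname GeneModel
#' @param x a `GeneModel` object.
#' @export
setGeneric("codingSeq", function(x) standardGeneric("codingSeq"))

#' @rdname GeneModel
#' @export
setGeneric("cdsIntervals", function(x) standardGeneric("cdsIntervals"))

#' @rdname GeneModel
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))
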