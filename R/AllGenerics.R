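#' @rdname OtuTable-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("otuTotals", function(x) standardGeneric("otuTotals"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' @rdname OtuTable-accessors
#' @export
setGeneric("otuOccurrence", function(x) standardGeneric("otuOccurrence"))

#' @rdname CurationReport-accessors
#' @export
setGeneric("reportSteps", function(x) standardGeneric("reportSteps"))

#' @rdname CurationReport-accessors
#' @export
setGeneric("removedOtus", function(x) standardGeneric("removedOtus"))

#' @rdname CurationReport-accessors
#' @export
setGeneric("removedSamples", function(x) standardGeneric("removedSamples"))

#' @rdname CurationReport-accessors
#' @export
setGeneric("zeroedCells", function(x) standardGeneric("zeroedCells"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("cleanTable", function(x) standardGeneric("cleanTable"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("switchedCells", function(x) standardGeneric("switchedCells"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("failedSampleIds", function(x) standardGeneric("failedSampleIds"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("contaminantOtuIds",
           function(x) standardGeneric("contaminantOtuIds"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("habitatMap", function(x) standardGeneric("habitatMap"))

#' @rdname SimTruth-accessors
#' @export
setGeneric("chimeraSeqIds", function(x) standardGeneric("chimeraSeqIds"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("ordCoordinates", function(x) standardGeneric("ordCoordinates"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("percentVariance", function(x) standardGeneric("percentVariance"))
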