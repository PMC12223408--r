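#' Construct an OtuTable
#'
#' @param counts OTU-by-sample matrix of non-negative integer read counts
#'   with unique rownames (OTU ids) and colnames (sample ids).
#' @param sampleData optional `data.frame` (or `DataFrame`) of per-sample
#'   metadata, one row per column of `counts`, rownames matching sample ids.
#'
#' @return an [OtuTable-class] object.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 7L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' ot <- OtuTable(m)
#' otuTotals(ot)
#' @export
OtuTable <- function(counts, sampleData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(sampleData)) {
        sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
    } else {
        sampleData <- S4Vectors::DataFrame(sampleData)
        if (is.null(rownames(sampleData)))
            rownames(sampleData) <- colnames(counts)
        miss <- setdiff(colnames(counts), rownames(sampleData))
        if (length(miss))
            stop("sampleData is missing samples: ", paste(miss, collapse = ", "))
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = sampleData)
    new("OtuTable", se)
}

#' Accessors for OtuTable
#'
#' `otuCounts` returns the integer count matrix; `otuIds` and `sampleIds`
#' its dimnames; `otuTotals`/`sampleDepths` the row/column sums;
#' `otuOccurrence` the number of samples in which each OTU has nonzero
#' reads.
#'
#' @param x an `OtuTable`.
#' @return see individual descriptions.
#' @name OtuTable-accessors
#' @aliases otuIds sampleIds otuTotals sampleDepths otuOccurrence otuCounts
NULL

#' @rdname OtuTable-accessors
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname OtuTable-accessors
#' @export
setMethod("otuIds", "OtuTable", function(x) rownames(x))

#' @rdname OtuTable-accessors
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x))

#' @rdname OtuTable-accessors
#' @export
setMethod("otuTotals", "OtuTable", function(x) rowSums(otuCounts(x)))

#' @rdname OtuTable-accessors
#' @export
setMethod("sampleDepths", "OtuTable", function(x) colSums(otuCounts(x)))

#' @rdname OtuTable-accessors
#' @export
setMethod("otuOccurrence", "OtuTable",
          function(x) rowSums(otuCounts(x) > 0))

setMethod("show", "OtuTable", function(object) {
    m <- otuCounts(object)
    cat(sprintf("OtuTable: %d OTUs x %d samples, %s reads\n",
                nrow(m), ncol(m), format(sum(m), big.mark = ",")))
    if (nrow(m) && ncol(m)) {
        tot <- rowSums(m)
        top <- head(order(tot, decreasing = TRUE), 3L)
        cat("  top OTUs:", paste(sprintf("%s (%d)", rownames(m)[top],
                                         tot[top]), collapse = ", "), "\n")
    }
    if (ncol(SummarizedExperiment::colData(object)))
        cat("  sample metadata:",
            paste(colnames(SummarizedExperiment::colData(object)),
                  collapse = ", "), "\n")
})

#' Accessors for CurationReport
#'
#' `reportSteps` returns the full audit data.frame; `removedOtus`,
#' `removedSamples` and `zeroedCells` subset it by step kind.
#'
#' @param x a `CurationReport`.
#' @name CurationReport-accessors
#' @aliases reportSteps removedOtus removedSamples zeroedCells
NULL

#' @rdname CurationReport-accessors
#' @export
setMethod("reportSteps", "CurationReport", function(x) x@steps)

#' @rdname CurationReport-accessors
#' @export
setMethod("removedOtus", "CurationReport", function(x)
    unique(x@steps$otu_id[x@steps$kind == "otu"]))

#' @rdname CurationReport-accessors
#' @export
setMethod("removedSamples", "CurationReport", function(x)
    unique(x@steps$sample_id[x@steps$kind == "sample"]))

#' @rdname CurationReport-accessors
#' @export
setMethod("zeroedCells", "CurationReport", function(x) {
    s <- x@steps
    s[s$kind == "cell" & s$value_after == 0 & s$value_before > 0, ,
      drop = FALSE]
})

setMethod("show", "CurationReport", function(object) {
    s <- object@steps
    cat(sprintf("CurationReport: %d entries over %d stages\n",
                nrow(s), length(unique(s$step))))
    for (st in unique(s$step)) {
        k <- s[s$step == st, ]
        cat(sprintf("  %-22s samples -%d, OTUs -%d, cells changed %d\n", st,
                    sum(k$kind == "sample"), sum(k$kind == "otu"),
                    sum(k$kind == "cell")))
    }
})

#' Accessors for SimTruth
#'
#' @param x a `SimTruth`.
#' @name SimTruth-accessors
#' @aliases cleanTable switchedCells failedSampleIds contaminantOtuIds
#'   habitatMap chimeraSeqIds
NULL

#' @rdname SimTruth-accessors
#' @export
setMethod("cleanTable", "SimTruth", function(x) x@cleanTable)

#' @rdname SimTruth-accessors
#' @export
setMethod("switchedCells", "SimTruth", function(x) x@switchedCells)

#' @rdname SimTruth-accessors
#' @export
setMethod("failedSampleIds", "SimTruth", function(x) x@failedSampleIds)

#' @rdname SimTruth-accessors
#' @export
setMethod("contaminantOtuIds", "SimTruth", function(x) x@contaminantOtuIds)

#' @rdname SimTruth-accessors
#' @export
setMethod("habitatMap", "SimTruth", function(x) x@habitatMap)

#' @rdname SimTruth-accessors
#' @export
setMethod("chimeraSeqIds", "SimTruth", function(x) x@chimeraSeqIds)

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:\n")
    cat("  clean table:", nrow(object@cleanTable), "OTUs x",
        ncol(object@cleanTable), "samples\n")
    cat("  contaminant OTUs:", length(object@contaminantOtuIds),
        " failed samples:", length(object@failedSampleIds),
        " switched read packets:", nrow(object@switchedCells), "\n")
})

#' Accessors for OrdinationResult
#'
#' @param x an `OrdinationResult`.
#' @name OrdinationResult-accessors
#' @aliases ordCoordinates eigenvalues percentVariance
NULL

#' @rdname OrdinationResult-accessors
#' @export
setMethod("ordCoordinates", "OrdinationResult", function(x) x@coordinates)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("eigenvalues", "OrdinationResult", function(x) x@eigenvalues)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("percentVariance", "OrdinationResult", function(x)
    x@percentVariance)

setMethod("show", "OrdinationResult", function(object) {
    cat(sprintf("OrdinationResult: %d samples, %d positive axes\n",
                nrow(object@coordinates), ncol(object@coordinates)))
    k <- min(3L, length(object@percentVariance))
    if (k)
        cat("  % variance:",
            paste(sprintf("%.1f", object@percentVariance[seq_len(k)]),
                  collapse = ", "), "...\n")
})

#' Construct curation parameters
#'
#' Convenience constructor for [CurationParams-class]; any threshold can be
#' overridden by name.
#'
#' @param ... named thresholds, see [CurationParams-class] slots
#'   (e.g. `minSampleReads = 500`).
#' @return a validated `CurationParams`.
#' @examples
#' curationParams(rarefactionDepth = 5000)
#' @export
curationParams <- function(...) {
    args <- list(...)
    known <- slotNames("CurationParams")
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    do.call(new, c(list("CurationParams"), args))
}

#' Construct a synthetic-community configuration
#'
#' @param ... named fields overriding [SimConfig-class] defaults
#'   (e.g. `nSamples = 10`, `seed = 42`).
#' @return a validated `SimConfig`.
#' @examples
#' simConfig(nSamples = 8, nFreshwaterOtus = 12, seed = 3)
#' @export
simConfig <- function(...) {
    args <- list(...)
    known <- slotNames("SimConfig")
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "))
    do.call(new, c(list("SimConfig"), args))
}
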