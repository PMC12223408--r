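#' @import methods
#' @importFrom stats rlnorm rmultinom runif rbinom setNames sd quantile
#' @importFrom utils read.delim write.table head adist
NULL

#' OtuTable: an OTU-by-sample read-count matrix with sample metadata
#'
#' `OtuTable` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"counts"` assay holding non-negative integer read counts, rows
#' being OTUs and columns samples. Sample metadata (location, site type,
#' substrate, pH, ...) lives in `colData` and follows the samples through
#' every curation step.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [OtuTable()] for construction, [runCuration()] for the curation
#'   cascade, [weightedUnifrac()] for beta diversity.
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(m)) msg <- c(msg, "counts contain NA")
        else {
            if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m))) msg <- c(msg, "counts must be integers")
        }
    }
    rn <- rownames(object); cn <- colnames(object)
    if ((is.null(rn) && nrow(object) > 0) || anyDuplicated(rn) ||
        any(!nzchar(rn)))
        msg <- c(msg, "OTU ids must be unique non-empty rownames")
    if ((is.null(cn) && ncol(object) > 0) || anyDuplicated(cn) ||
        any(!nzchar(cn)))
        msg <- c(msg, "sample ids must be unique non-empty colnames")
    if (length(msg)) msg else TRUE
})

#' Parameters of the OTU-table curation cascade
#'
#' Holds every threshold of the curation cascade. Defaults are the values
#' used for the freshwater foraminifera survey the package was written for:
#' samples need at least 500 unrarefied reads, OTUs at least 100 unrarefied
#' reads and at least 2 occurrences, rarefaction is at 10,000 reads,
#' index-switch correction zeroes cells below 20 reads in OTUs with more than
#' 1000 total rarefied reads and single-read cells in all other OTUs, and the
#' final filter keeps OTUs with more than 20 total rarefied reads.
#'
#' @slot minSampleReads minimum unrarefied column sum; smaller samples are
#'   treated as failed and dropped (strict: `< minSampleReads` drops).
#' @slot minOtuReads minimum unrarefied row sum (strict: `< minOtuReads`
#'   drops).
#' @slot minOtuOccurrence minimum number of samples with nonzero reads.
#' @slot rarefactionDepth reads drawn per sample without replacement;
#'   shallower samples are kept whole.
#' @slot bigOtuTotal rarefied row-sum boundary between the two index-switch
#'   rules; rows with total strictly greater fall under rule 1.
#' @slot bigOtuCellFloor rule 1 zeroes cells with `0 < value <
#'   bigOtuCellFloor`.
#' @slot smallOtuCellFloor rule 2 zeroes cells with `value <=
#'   smallOtuCellFloor` (default 1: exactly single-read cells).
#' @slot finalMinOtuReads final filter keeps OTUs with row sum strictly
#'   greater than this.
#'
#' @export
setClass("CurationParams", representation(
    minSampleReads = "numeric",
    minOtuReads = "numeric",
    minOtuOccurrence = "numeric",
    rarefactionDepth = "numeric",
    bigOtuTotal = "numeric",
    bigOtuCellFloor = "numeric",
    smallOtuCellFloor = "numeric",
    finalMinOtuReads = "numeric"
), prototype(
    minSampleReads = 500,
    minOtuReads = 100,
    minOtuOccurrence = 2,
    rarefactionDepth = 10000,
    bigOtuTotal = 1000,
    bigOtuCellFloor = 20,
    smallOtuCellFloor = 1,
    finalMinOtuReads = 20
))

setValidity("CurationParams", function(object) {
    v <- c(object@minSampleReads, object@minOtuReads, object@minOtuOccurrence,
           object@rarefactionDepth, object@bigOtuTotal, object@bigOtuCellFloor,
           object@smallOtuCellFloor, object@finalMinOtuReads)
    if (any(!is.finite(v)) || any(v < 0))
        return("all curation parameters must be finite and >= 0")
    if (object@bigOtuCellFloor >= object@bigOtuTotal)
        return("bigOtuCellFloor must be smaller than bigOtuTotal")
    TRUE
})

#' Ordered audit trail of a curation run
#'
#' Every removal and cell zeroing performed by the curation functions is
#' recorded as one row of `steps`, in execution order. Replaying a report on
#' the input table with [applyCurationReport()] reproduces the output table
#' bit-exactly, including the stochastic rarefaction draws (whose realised
#' per-cell values are logged as `cell` entries).
#'
#' @slot steps a `data.frame` with columns `step` (stage name), `kind` (one
#'   of `"sample"`, `"otu"`, `"cell"`, `"note"`), `otu_id`, `sample_id`,
#'   `reason`, `value_before`, `value_after`.
#' @slot params the `CurationParams` in force.
#' @slot seed integer seed used for rarefaction, `NA` if none.
#' @export
setClass("CurationReport", representation(
    steps = "data.frame", params = "CurationParams", seed = "integer"
), prototype(
    steps = data.frame(step = character(), kind = character(),
                       otu_id = character(), sample_id = character(),
                       reason = character(), value_before = numeric(),
                       value_after = numeric(), stringsAsFactors = FALSE),
    params = new("CurationParams"), seed = NA_integer_
))

setValidity("CurationReport", function(object) {
    need <- c("step", "kind", "otu_id", "sample_id", "reason",
              "value_before", "value_after")
    if (!all(need %in% names(object@steps)))
        return(paste("steps must have columns:", paste(need, collapse = ", ")))
    bad <- setdiff(unique(object@steps$kind),
                   c("sample", "otu", "cell", "note"))
    if (length(bad)) return(paste("unknown step kind:", paste(bad, collapse = ",")))
    TRUE
})

#' Configuration of the synthetic amplicon community generator
#'
#' Defaults emulate the structure of a small freshwater-foraminifera survey:
#' 30 retained samples drawn from 4 locations with a few site types each,
#' ~60 freshwater OTUs under a heavy-tailed (log-normal) abundance law so
#' that one OTU typically carries about a third of all reads, sample depths
#' log-uniform between roughly 700 and 300,000 reads, a handful of failed
#' (<500 read) samples, a few marine contaminant OTUs, low-level index
#' switching, and a small fraction of chimeric sequences.
#'
#' @slot nSamples number of non-failed samples.
#' @slot nLocations number of sampling locations.
#' @slot nSiteTypesPerLocation site types within each location.
#' @slot nFreshwaterOtus true freshwater OTU richness.
#' @slot nContaminantOtus marine contaminant OTUs spiked into random samples.
#' @slot abundanceSigma log-normal sdlog of OTU base abundances
#'   (dimensionless); 2.5 gives the observed level of single-OTU dominance.
#' @slot specificityFraction probability that a freshwater OTU is restricted
#'   to exactly one location.
#' @slot depthLog10Range length-2 numeric, min and max log10 sample depth.
#' @slot failedSampleFraction fraction of additional samples simulated as
#'   failed libraries (depths uniform on [50, 499]).
#' @slot switchRate per-read probability of index switching to a uniformly
#'   chosen other sample.
#' @slot chimeraRate chimeric sequences generated per leaf sequence
#'   (ceiling(chimeraRate * leaves) chimeras).
#' @slot seqLength amplicon length in bases.
#' @slot subsRate expected substitutions per site multiplying the tree's
#'   branch lengths.
#' @slot seed master seed; fixes every downstream draw.
#' @export
setClass("SimConfig", representation(
    nSamples = "numeric", nLocations = "numeric",
    nSiteTypesPerLocation = "numeric", nFreshwaterOtus = "numeric",
    nContaminantOtus = "numeric", abundanceSigma = "numeric",
    specificityFraction = "numeric", depthLog10Range = "numeric",
    failedSampleFraction = "numeric", switchRate = "numeric",
    chimeraRate = "numeric", seqLength = "numeric", subsRate = "numeric",
    seed = "numeric"
), prototype(
    nSamples = 30, nLocations = 4, nSiteTypesPerLocation = 3,
    nFreshwaterOtus = 60, nContaminantOtus = 6, abundanceSigma = 2.5,
    specificityFraction = 0.5, depthLog10Range = c(log10(700), log10(300000)),
    failedSampleFraction = 0.2, switchRate = 0.002, chimeraRate = 0.05,
    seqLength = 250, subsRate = 0.2, seed = 1
))

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@specificityFraction, object@failedSampleFraction,
               object@switchRate, object@chimeraRate)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    cnt <- c(object@nSamples, object@nLocations, object@nSiteTypesPerLocation,
             object@nFreshwaterOtus, object@seqLength)
    if (any(cnt < 1) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be integers >= 1")
    if (object@nContaminantOtus < 0)
        msg <- c(msg, "nContaminantOtus must be >= 0")
    if (length(object@depthLog10Range) != 2 ||
        object@depthLog10Range[1] > object@depthLog10Range[2])
        msg <- c(msg, "depthLog10Range must be (min, max) with min <= max")
    if (object@abundanceSigma < 0 || object@subsRate < 0)
        msg <- c(msg, "abundanceSigma and subsRate must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Record of everything the generator did before corruption, so downstream
#' filters can be scored: the clean table, which OTUs are contaminants,
#' every index-switched read movement, which samples were simulated as
#' failed libraries, which sequences are chimeric, the phylogeny, and the
#' habitat (location) restriction of each freshwater OTU.
#'
#' @slot cleanTable `OtuTable` before index switching.
#' @slot contaminantOtuIds character vector of marine contaminant OTU ids.
#' @slot switchedCells `data.frame` with columns `otu_id`, `from_sample`,
#'   `to_sample`, `reads`: every read packet moved by index switching.
#' @slot failedSampleIds samples observably failed in the corrupted table
#'   (fewer than 500 reads after index switching; drawn depths are below
#'   500, but bleed-in can occasionally push a borderline library over).
#' @slot chimeraSeqIds ids of chimeric sequences (empty until sequences are
#'   simulated).
#' @slot chimeraInfo `data.frame` `seq_id`, `parent_a`, `parent_b`,
#'   `breakpoint`.
#' @slot tree rooted `phylo` covering all OTUs.
#' @slot habitatMap named list: freshwater OTU id -> allowed locations.
#' @export
setClass("SimTruth", representation(
    cleanTable = "OtuTable", contaminantOtuIds = "character",
    switchedCells = "data.frame", failedSampleIds = "character",
    chimeraSeqIds = "character", chimeraInfo = "data.frame",
    tree = "ANY", habitatMap = "list"
))

#' Result of a principal coordinates analysis
#'
#' @slot coordinates samples-by-axes matrix of principal coordinates
#'   (axes only for positive eigenvalues).
#' @slot eigenvalues all eigenvalues of the doubly-centred Gower matrix,
#'   descending (negative ones reported, not embedded).
#' @slot percentVariance percent of the positive-eigenvalue sum captured by
#'   each positive axis; sums to 100.
#' @export
setClass("OrdinationResult", representation(
    coordinates = "matrix", eigenvalues = "numeric",
    percentVariance = "numeric"
))

setValidity("OrdinationResult", function(object) {
    if (is.unsorted(rev(object@eigenvalues)))
        return("eigenvalues must be in descending order")
    if (length(object@percentVariance) &&
        abs(sum(object@percentVariance) - 100) > 1e-6)
        return("percentVariance must sum to 100")
    TRUE
})
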