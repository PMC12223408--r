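emptySteps <- function() {
    data.frame(step = character(), kind = character(), otu_id = character(),
               sample_id = character(), reason = character(),
               value_before = numeric(), value_after = numeric(),
               stringsAsFactors = FALSE)
}

stepRows <- function(step, kind, otu_id = NA_character_,
                     sample_id = NA_character_, reason,
                     value_before = NA_real_, value_after = NA_real_) {
    n <- max(length(otu_id), length(sample_id), length(reason),
             length(value_before), length(value_after))
    if (n == 0) return(emptySteps())
    data.frame(step = step, kind = kind,
               otu_id = rep_len(as.character(otu_id), n),
               sample_id = rep_len(as.character(sample_id), n),
               reason = rep_len(reason, n),
               value_before = rep_len(as.numeric(value_before), n),
               value_after = rep_len(as.numeric(value_after), n),
               stringsAsFactors = FALSE)
}

mkReport <- function(steps, params, seed = NA_integer_) {
    new("CurationReport", steps = steps, params = params,
        seed = as.integer(seed))
}

#' Unrarefied sample/OTU filtering to fixpoint
#'
#' Repeats two sweeps until nothing changes: (1) drop samples whose total
#' unrarefied reads fall below `minSampleReads` (likely failed libraries);
#' (2) drop OTUs with fewer than `minOtuReads` total reads or present in
#' fewer than `minOtuOccurrence` samples. Removing OTUs can push further
#' samples under the read floor (and vice versa), hence the fixpoint
#' iteration; every pass is logged.
#'
#' @param table an [OtuTable-class].
#' @param params a [curationParams()] object.
#' @return list with `table` (filtered) and `report`
#'   ([CurationReport-class]). An empty result is legal.
#' @examples
#' m <- matrix(c(600L, 10L, 300L, 5L), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' filterUnrarefied(OtuTable(m))$table
#' @export
filterUnrarefied <- function(table, params = curationParams()) {
    stopifnot(is(table, "OtuTable"), is(params, "CurationParams"))
    steps <- emptySteps()
    pass <- 0L
    repeat {
        pass <- pass + 1L
        changed <- FALSE
        depths <- sampleDepths(table)
        badS <- names(depths)[depths < params@minSampleReads]
        if (length(badS)) {
            steps <- rbind(steps, stepRows(
                "unrarefied_filter", "sample", sample_id = badS,
                reason = sprintf("pass %d: unrarefied reads < %d", pass,
                                 params@minSampleReads),
                value_before = depths[badS], value_after = 0))
            table <- table[, setdiff(sampleIds(table), badS)]
            changed <- TRUE
        }
        tot <- otuTotals(table)
        occ <- otuOccurrence(table)
        badO <- names(tot)[tot < params@minOtuReads |
                           occ < params@minOtuOccurrence]
        if (length(badO)) {
            steps <- rbind(steps, stepRows(
                "unrarefied_filter", "otu", otu_id = badO,
                reason = sprintf("pass %d: reads < %d or occurrence < %d",
                                 pass, params@minOtuReads,
                                 params@minOtuOccurrence),
                value_before = tot[badO], value_after = 0))
            table <- table[setdiff(otuIds(table), badO), ]
            changed <- TRUE
        }
        if (!changed) break
    }
    list(table = table, report = mkReport(steps, params))
}

#' Remove flagged contaminant OTUs and contaminated samples
#'
#' Drops externally identified OTUs (e.g. marine contaminants spotted by
#' phylogenetic placement or BLAST) and samples (e.g. heavily contaminated
#' libraries). Ids not present in the table are logged as no-ops, never an
#' error.
#'
#' @param table an [OtuTable-class].
#' @param flaggedOtus,flaggedSamples character vectors of ids (may be
#'   empty).
#' @param params parameters recorded in the report.
#' @return list with `table` and `report`.
#' @export
dropFlagged <- function(table, flaggedOtus = character(),
                        flaggedSamples = character(),
                        params = curationParams()) {
    stopifnot(is(table, "OtuTable"))
    steps <- emptySteps()
    hitO <- intersect(flaggedOtus, otuIds(table))
    missO <- setdiff(flaggedOtus, otuIds(table))
    hitS <- intersect(flaggedSamples, sampleIds(table))
    missS <- setdiff(flaggedSamples, sampleIds(table))
    if (length(hitO))
        steps <- rbind(steps, stepRows(
            "drop_flagged", "otu", otu_id = hitO,
            reason = "flagged contaminant OTU",
            value_before = otuTotals(table)[hitO], value_after = 0))
    if (length(hitS))
        steps <- rbind(steps, stepRows(
            "drop_flagged", "sample", sample_id = hitS,
            reason = "flagged contaminated sample",
            value_before = sampleDepths(table)[hitS], value_after = 0))
    for (id in c(missO, missS))
        steps <- rbind(steps, stepRows(
            "drop_flagged", "note", reason = sprintf(
                "flagged id '%s' not present; no-op", id)))
    table <- table[setdiff(otuIds(table), hitO),
                   setdiff(sampleIds(table), hitS)]
    list(table = table, report = mkReport(steps, params))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each sample with more reads than `depth` is subsampled to exactly
#' `depth` reads drawn without replacement (a multivariate hypergeometric
#' draw over its OTU counts). Samples at or below `depth` are left
#' untouched, so shallow samples keep all their reads. Each sample's draw
#' is sub-seeded from the master seed and the sample id, making the result
#' reproducible and independent of column order.
#'
#' @param table an [OtuTable-class].
#' @param depth target reads per sample (> 0), default 10,000.
#' @param seed integer master seed.
#' @return the rarefied [OtuTable-class].
#' @examples
#' m <- matrix(c(900L, 100L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' sampleDepths(rarefy(OtuTable(m), depth = 100, seed = 1))
#' @export
rarefy <- function(table, depth = 10000, seed = 1) {
    stopifnot(is(table, "OtuTable"))
    if (!is.finite(depth) || depth <= 0) stop("depth must be > 0")
    m <- otuCounts(table)
    for (j in seq_len(ncol(m))) {
        cs <- sum(m[, j])
        if (cs <= depth) next
        sid <- colnames(m)[j]
        reads <- rep.int(seq_len(nrow(m)), m[, j])
        keep <- withSeed(stableSeed(seed, sid),
                         sample(reads, size = depth, replace = FALSE))
        m[, j] <- tabulate(keep, nbins = nrow(m))
    }
    storage.mode(m) <- "integer"
    out <- table
    SummarizedExperiment::assay(out, "counts") <- m
    validObject(out)
    out
}

#' Zero out reads attributed to index switching
#'
#' Index switching (tag jumping) on multiplexed runs scatters a small
#' fraction of an abundant OTU's reads into the wrong samples, producing
#' spurious low-count cells. Two rules are applied to the rarefied table,
#' with row totals computed once on the input: (1) rows with more than
#' `bigOtuTotal` (default 1000) total reads have every cell with fewer than
#' `bigOtuCellFloor` (default 20) reads zeroed; (2) all other rows
#' (totals at or below the boundary) have single-read cells zeroed. Every
#' zeroed cell is logged.
#'
#' @param table the rarefied [OtuTable-class].
#' @param params a [curationParams()] object.
#' @return list with `table` and `report`.
#' @examples
#' m <- matrix(c(19L, 20L, 1461L), 1, 3,
#'             dimnames = list("big", c("s1", "s2", "s3")))
#' otuCounts(correctIndexSwitching(OtuTable(m))$table)
#' @export
correctIndexSwitching <- function(table, params = curationParams()) {
    stopifnot(is(table, "OtuTable"), is(params, "CurationParams"))
    m <- otuCounts(table)
    tot <- rowSums(m)
    steps <- emptySteps()
    for (i in seq_len(nrow(m))) {
        if (tot[i] > params@bigOtuTotal) {
            hit <- which(m[i, ] > 0 & m[i, ] < params@bigOtuCellFloor)
            reason <- sprintf("rule 1: OTU total %d > %d, cell < %d reads",
                              tot[i], params@bigOtuTotal,
                              params@bigOtuCellFloor)
        } else {
            hit <- which(m[i, ] > 0 & m[i, ] <= params@smallOtuCellFloor)
            reason <- sprintf("rule 2: OTU total %d <= %d, cell <= %d read",
                              tot[i], params@bigOtuTotal,
                              params@smallOtuCellFloor)
        }
        if (length(hit)) {
            steps <- rbind(steps, stepRows(
                "index_switch_correction", "cell",
                otu_id = rownames(m)[i], sample_id = colnames(m)[hit],
                reason = reason, value_before = m[i, hit], value_after = 0))
            m[i, hit] <- 0L
        }
    }
    out <- table
    SummarizedExperiment::assay(out, "counts") <- m
    list(table = out, report = mkReport(steps, params))
}

#' Final rarefied-abundance OTU filter
#'
#' Keeps only OTUs with strictly more than `finalMinOtuReads` (default 20)
#' total rarefied reads.
#'
#' @param table post-correction [OtuTable-class].
#' @param params a [curationParams()] object.
#' @return list with `table` and `report`.
#' @export
finalOtuFilter <- function(table, params = curationParams()) {
    stopifnot(is(table, "OtuTable"), is(params, "CurationParams"))
    tot <- otuTotals(table)
    bad <- names(tot)[tot <= params@finalMinOtuReads]
    steps <- if (length(bad)) stepRows(
        "final_otu_filter", "otu", otu_id = bad,
        reason = sprintf("total rarefied reads <= %d",
                         params@finalMinOtuReads),
        value_before = tot[bad], value_after = 0) else emptySteps()
    list(table = table[setdiff(otuIds(table), bad), ],
         report = mkReport(steps, params))
}

#' Run the full OTU-table curation cascade
#'
#' Composes, in order: unrarefied filtering to fixpoint
#' ([filterUnrarefied()]); removal of flagged contaminant OTUs and samples
#' ([dropFlagged()]); a full re-check of the unrarefied thresholds;
#' seeded rarefaction ([rarefy()]); index-switching correction
#' ([correctIndexSwitching()]); and the final abundance filter
#' ([finalOtuFilter()]). The concatenated [CurationReport-class] records
#' every removal and cell change, including the realised rarefaction draws,
#' so that [applyCurationReport()] replays the run bit-exactly. The
#' unrarefied read floor applies to unrarefied data only: samples whose
#' totals fall below it merely through rarefaction or zeroing are retained.
#'
#' @param table the unrarefied [OtuTable-class].
#' @param flaggedOtus,flaggedSamples externally identified contaminants.
#' @param params a [curationParams()] object.
#' @param seed master seed for rarefaction.
#' @return list with `table` (final curated [OtuTable-class]) and `report`.
#' @export
runCuration <- function(table, flaggedOtus = character(),
                        flaggedSamples = character(),
                        params = curationParams(), seed = 1) {
    s1 <- filterUnrarefied(table, params)
    s2 <- dropFlagged(s1$table, flaggedOtus, flaggedSamples, params)
    s3 <- filterUnrarefied(s2$table, params)
    s3$report@steps$step[] <- "unrarefied_recheck"
    rare <- rarefy(s3$table, depth = params@rarefactionDepth, seed = seed)
    mIn <- otuCounts(s3$table); mOut <- otuCounts(rare)
    ch <- which(mIn != mOut, arr.ind = TRUE)
    rareSteps <- if (nrow(ch)) stepRows(
        "rarefy", "cell", otu_id = rownames(mIn)[ch[, 1]],
        sample_id = colnames(mIn)[ch[, 2]],
        reason = sprintf("rarefied to %d reads",
                         as.integer(params@rarefactionDepth)),
        value_before = mIn[ch], value_after = mOut[ch]) else emptySteps()
    s5 <- correctIndexSwitching(rare, params)
    s6 <- finalOtuFilter(s5$table, params)
    steps <- rbind(s1$report@steps, s2$report@steps, s3$report@steps,
                   rareSteps, s5$report@steps, s6$report@steps)
    list(table = s6$table, report = mkReport(steps, params, seed))
}

#' Replay a curation report on its input table
#'
#' Applies a [CurationReport-class] entry by entry — sample removals, OTU
#' removals and cell changes in their recorded order — to the table the
#' curation started from. The result reproduces the curated table
#' bit-exactly, which makes the report a complete, independently checkable
#' audit of the cascade.
#'
#' @param table the original input [OtuTable-class].
#' @param report a [CurationReport-class].
#' @return the replayed [OtuTable-class].
#' @export
applyCurationReport <- function(table, report) {
    stopifnot(is(table, "OtuTable"), is(report, "CurationReport"))
    s <- report@steps
    for (r in seq_len(nrow(s))) {
        kind <- s$kind[r]
        if (kind == "sample") {
            table <- table[, setdiff(sampleIds(table), s$sample_id[r])]
        } else if (kind == "otu") {
            table <- table[setdiff(otuIds(table), s$otu_id[r]), ]
        } else if (kind == "cell") {
            m <- otuCounts(table)
            m[s$otu_id[r], s$sample_id[r]] <- as.integer(s$value_after[r])
            SummarizedExperiment::assay(table, "counts") <- m
        }
    }
    table
}
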