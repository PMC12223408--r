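#' Assemble a pipeline configuration
#'
#' A flat list controlling [runPipeline()]: which stages run, the
#' generator settings, every curation threshold, the UniFrac/PCoA flags
#' and the master seed. Unknown fields are rejected. The same structure
#' can be read from a YAML file with [readPipelineConfig()].
#'
#' @param simulate,callOtus,curate,analyze stage toggles.
#' @param sim a [simConfig()] object (used when `simulate` is on).
#' @param params a [curationParams()] object.
#' @param flaggedOtus,flaggedSamples ids to drop at curation; when
#'   `simulate` is on and these are `NULL`, the generator's known
#'   contaminant OTUs and failed samples stand in for the survey's
#'   externally flagged lists.
#' @param normalized normalised weighted UniFrac (default TRUE).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return a `list` of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulate = TRUE, callOtus = FALSE, curate = TRUE,
                           analyze = TRUE, sim = simConfig(),
                           params = curationParams(),
                           flaggedOtus = NULL, flaggedSamples = NULL,
                           normalized = TRUE, seed = 1) {
    structure(list(simulate = simulate, callOtus = callOtus,
                   curate = curate, analyze = analyze, sim = sim,
                   params = params, flaggedOtus = flaggedOtus,
                   flaggedSamples = flaggedSamples, normalized = normalized,
                   seed = as.integer(seed)),
              class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring [pipelineConfig()]; generator fields live under
#' `sim:` and curation thresholds under `params:`.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    sim <- do.call(simConfig, as.list(y$sim %||% list()))
    params <- do.call(curationParams, as.list(y$params %||% list()))
    keep <- intersect(names(y), c("simulate", "callOtus", "curate",
                                  "analyze", "flaggedOtus",
                                  "flaggedSamples", "normalized", "seed"))
    do.call(pipelineConfig,
            c(y[keep], list(sim = sim, params = params)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

paramFingerprint <- function(config) {
    p <- config$params
    sprintf("seed=%d depth=%d minSample=%d minOtu=%d occ=%d final=%d norm=%s",
            config$seed, as.integer(p@rarefactionDepth),
            as.integer(p@minSampleReads), as.integer(p@minOtuReads),
            as.integer(p@minOtuOccurrence), as.integer(p@finalMinOtuReads),
            config$normalized)
}

#' Run the full pipeline and write every artifact
#'
#' Executes the enabled stages in order — simulate, call OTUs, curate,
#' analyze — writing each stage's outputs plus a YAML run manifest
#' (package version, seed, parameters, md5 checksums of every written
#' file). Identical configurations produce identical outputs.
#'
#' When `simulate` is off, `table`, `tree` and `metadata` must be supplied
#' (paths or objects). When `callOtus` is on, reads are re-called from the
#' simulated (or supplied) sequences instead of using the simulated table
#' directly.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory, created if needed.
#' @param table,tree,metadata inputs for non-simulated runs: an
#'   [OtuTable-class] or TSV path, a `phylo` or Newick path, a
#'   `data.frame` or TSV path.
#' @return invisibly, a list with the final `table`, curation `report`,
#'   `dist`, `ordination`, `occupancy` and the `manifest` path.
#' @export
runPipeline <- function(config, outdir, table = NULL, tree = NULL,
                        metadata = NULL) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- paramFingerprint(config)
    cm <- c(paste("foramMetabar", as.character(utils::packageVersion(
        "foramMetabar"))), fp)
    written <- character()
    put <- function(f) { written <<- c(written, f); f }

    truth <- NULL
    if (config$simulate) {
        simc <- config$sim
        simc@seed <- config$seed
        sim <- simulateDataset(simc)
        table <- sim$table
        truth <- sim$truth
        tree <- truth@tree
        metadata <- as.data.frame(SummarizedExperiment::colData(table))
        writeOtuTable(table, put(file.path(outdir, "otu_table_raw.tsv")), cm)
        writeNewick(tree, put(file.path(outdir, "tree.nwk")))
        writeTsv(metadata, put(file.path(outdir, "metadata.tsv")), cm)
        derep <- data.frame(id = names(sim$sequences),
                            sequence = unname(sim$sequences),
                            sample = "reference", count = 1L)
        writeFastaReads(derep, put(file.path(outdir, "sequences.fasta")))
        writeTsv(truth@switchedCells,
                 put(file.path(outdir, "truth_switched_cells.tsv")), cm)
        yaml::write_yaml(list(
            contaminant_otu_ids = truth@contaminantOtuIds,
            failed_sample_ids = truth@failedSampleIds,
            chimera_seq_ids = truth@chimeraSeqIds,
            habitat_map = truth@habitatMap),
            put(file.path(outdir, "truth.yaml")))
        writeOtuTable(truth@cleanTable,
                      put(file.path(outdir, "truth_clean_table.tsv")), cm)
    } else {
        if (is.character(table)) table <- readOtuTable(table)
        if (is.character(tree)) tree <- readNewick(tree)
        if (is.character(metadata)) metadata <- readTsv(metadata)
        if (is.null(table)) stop("stage 'curate': no input table")
    }

    if (config$callOtus) {
        if (config$simulate) {
            reads <- expandReads(table, truth, config$sim)
        } else stop("stage 'call-otus': reads input not supplied")
        called <- callOtus(reads)
        writeOtuTable(called$table,
                      put(file.path(outdir, "otu_table_called.tsv")), cm)
        writeTsv(called$log,
                 put(file.path(outdir, "otu_calling_log.tsv")), cm)
    }

    report <- NULL
    if (config$curate) {
        fo <- config$flaggedOtus %||%
            if (!is.null(truth)) truth@contaminantOtuIds else character()
        fs <- config$flaggedSamples %||% character()
        cur <- runCuration(table, flaggedOtus = fo, flaggedSamples = fs,
                           params = config$params, seed = config$seed)
        table <- cur$table
        report <- cur$report
        writeOtuTable(table,
                      put(file.path(outdir, "otu_table_curated.tsv")), cm)
        writeCurationReport(report,
                            put(file.path(outdir, "curation_report.tsv")), cm)
    }

    D <- NULL; ord <- NULL; occ <- NULL
    if (config$analyze) {
        if (is.null(tree)) stop("stage 'analyze': no tree supplied")
        D <- weightedUnifrac(table, tree, normalized = config$normalized)
        ord <- pcoaOrdination(D)
        occ <- occupancySummary(table)
        writeDistanceMatrix(D,
                            put(file.path(outdir, "unifrac_dist.tsv")), cm)
        writeOrdination(ord, file.path(outdir, "pcoa"), cm)
        written <- c(written, file.path(outdir, c("pcoa_coords.tsv",
                                                  "pcoa_eigen.tsv")))
        writeTsv(classifyTable(table),
                 put(file.path(outdir, "abundance_classes.tsv")), cm)
        writeTsv(occ$otus, put(file.path(outdir, "occupancy.tsv")), cm)
        writeTsv(data.frame(location = names(occ$locationRichness),
                            richness = occ$locationRichness),
                 put(file.path(outdir, "location_richness.tsv")), cm)
    }

    manifest <- file.path(outdir, "manifest.yaml")
    yaml::write_yaml(list(
        package = "foramMetabar",
        version = as.character(utils::packageVersion("foramMetabar")),
        seed = config$seed,
        fingerprint = fp,
        stages = list(simulate = config$simulate, callOtus = config$callOtus,
                      curate = config$curate, analyze = config$analyze),
        checksums = as.list(tools::md5sum(sort(unique(written))))),
        manifest)
    invisible(list(table = table, report = report, dist = D,
                   ordination = ord, occupancy = occ, manifest = manifest))
}

# turn a simulated table + sequences into a labelled read set for the OTU
# caller, at the table's counts, with chimeric reads appended at counts
# proportional to their parents
expandReads <- function(table, truth, simc) {
    m <- otuCounts(table)
    seqs <- simulateSequences(truth@tree, simc@seqLength, simc@subsRate,
                              simc@chimeraRate,
                              seed = stableSeed(simc@seed, "sequences"))
    rows <- list()
    for (i in rownames(m)) for (j in colnames(m)) {
        if (m[i, j] == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
            sequence = seqs$sequences[[i]], sample = j, count = m[i, j],
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
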