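#' Simulate a rooted phylogeny for a synthetic community
#'
#' Draws a random rooted binary tree with strictly positive branch lengths
#' and leaves labelled `OTU1 ... OTUn`. Deterministic for a given seed.
#'
#' @param nTaxa number of leaves, at least 2.
#' @param seed integer seed.
#' @param labels optional character vector of leaf labels (length `nTaxa`).
#' @return an [ape::rtree()]-style rooted `phylo` object.
#' @examples
#' tr <- simulateTree(6, seed = 1)
#' ape::is.rooted(tr)
#' @export
simulateTree <- function(nTaxa, seed, labels = NULL) {
    nTaxa <- assertCount(nTaxa, "nTaxa", min = 2)
    if (is.null(labels)) labels <- paste0("OTU", seq_len(nTaxa))
    if (length(labels) != nTaxa || anyDuplicated(labels))
        stop("labels must be ", nTaxa, " unique ids")
    withSeed(seed, {
        tr <- ape::rtree(nTaxa, rooted = TRUE)
        # rtree branch lengths are runif(0, 1); keep them away from zero
        tr$edge.length <- pmax(tr$edge.length, 1e-3)
        tr$tip.label <- labels
        tr
    })
}

#' Evolve sequences along a tree and append chimeric artifacts
#'
#' A random root sequence is evolved down the tree under a single-rate,
#' equal-frequency (Jukes-Cantor) substitution model, giving one sequence
#' per leaf. `ceiling(chimeraRate * nLeaves)` chimeras are then formed, each
#' as the prefix of one leaf sequence joined to the suffix of another at a
#' breakpoint leaving both segments at least 20% of the sequence length;
#' parent pairs and breakpoints are recorded.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param seqLength amplicon length in bases (>= 50).
#' @param subsRate expected substitutions per site multiplying the tree's
#'   branch lengths; 0 reproduces the root sequence at every leaf.
#' @param chimeraRate chimeras per leaf sequence, in [0, 1].
#' @param seed integer seed.
#' @return a list with `sequences` (named character, one per leaf, uppercase
#'   ACGT), `chimeras` (named character) and `chimeraInfo` (`data.frame`
#'   with `seq_id`, `parent_a`, `parent_b`, `breakpoint`).
#' @examples
#' tr <- simulateTree(4, seed = 1)
#' s <- simulateSequences(tr, seqLength = 60, subsRate = 0.1,
#'                        chimeraRate = 0, seed = 2)
#' nchar(s$sequences[[1]])
#' @export
simulateSequences <- function(tree, seqLength, subsRate, chimeraRate, seed) {
    if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
    seqLength <- assertCount(seqLength, "seqLength", min = 50)
    if (chimeraRate < 0 || chimeraRate > 1)
        stop("chimeraRate must lie in [0, 1]")
    if (subsRate < 0) stop("subsRate must be >= 0")
    withSeed(seed, {
        sim <- phangorn::simSeq(tree, l = seqLength, rate = subsRate)
        chars <- toupper(as.character(sim))
        seqs <- setNames(apply(chars, 1, paste0, collapse = ""),
                         rownames(chars))[tree$tip.label]
        nChim <- ceiling(chimeraRate * length(seqs))
        info <- data.frame(seq_id = character(), parent_a = character(),
                           parent_b = character(), breakpoint = integer(),
                           stringsAsFactors = FALSE)
        chim <- character()
        if (nChim > 0) {
            lo <- ceiling(0.2 * seqLength)
            hi <- floor(0.8 * seqLength)
            for (i in seq_len(nChim)) {
                par <- sample(names(seqs), 2L)
                k <- if (lo < hi) sample(lo:hi, 1L) else lo
                cs <- paste0(substr(seqs[[par[1]]], 1L, k),
                             substr(seqs[[par[2]]], k + 1L, seqLength))
                id <- paste0("chimera", i)
                chim[id] <- cs
                info <- rbind(info, data.frame(
                    seq_id = id, parent_a = par[1], parent_b = par[2],
                    breakpoint = k, stringsAsFactors = FALSE))
            }
        }
        list(sequences = seqs, chimeras = chim, chimeraInfo = info)
    })
}

#' Simulate a full metabarcoding dataset with ground truth
#'
#' Generates a phylogeny, leaf sequences (plus chimeras), sample metadata and
#' an OTU-by-sample read-count table with the statistical structure of a
#' small freshwater-foraminifera amplicon survey, then corrupts it with
#' index switching. Every corruption is recorded in a [SimTruth-class]
#' ledger so downstream filters can be scored against the truth.
#'
#' The generative model: per-OTU base abundances are log-normal (heavy tail,
#' so one OTU typically dominates); a `specificityFraction` of freshwater
#' OTUs are restricted to a single location (zero reads elsewhere in the
#' clean table); sample depths are log-uniform over `depthLog10Range`,
#' except failed libraries drawn uniformly on [50, 499] reads; sample counts
#' are multinomial over the habitat-masked abundances; marine contaminant
#' OTUs are spiked into a random subset of samples at roughly half a percent
#' of sample depth; finally each read independently switches to a uniformly
#' chosen other sample with probability `switchRate`, with every packet of
#' moved reads logged.
#'
#' @param config a [simConfig()] object.
#' @return a list with elements `table` (the corrupted [OtuTable-class],
#'   sample metadata in `colData`), `truth` (a [SimTruth-class]) and
#'   `sequences` (named character: leaf sequences then chimeras).
#' @examples
#' sim <- simulateDataset(simConfig(nSamples = 6, nFreshwaterOtus = 10,
#'                                  nContaminantOtus = 2, seed = 7))
#' sim$table
#' @export
simulateDataset <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    nF <- as.integer(config@nFreshwaterOtus)
    nC <- as.integer(config@nContaminantOtus)
    nOtu <- nF + nC
    otuIdsF <- paste0("OTU", seq_len(nF))
    otuIdsC <- if (nC > 0) paste0("MARINE", seq_len(nC)) else character()
    allIds <- c(otuIdsF, otuIdsC)

    tree <- simulateTree(nOtu, seed = stableSeed(config@seed, "tree"),
                         labels = allIds)
    seqs <- simulateSequences(tree, config@seqLength, config@subsRate,
                              config@chimeraRate,
                              seed = stableSeed(config@seed, "sequences"))

    withSeed(stableSeed(config@seed, "dataset"), {
        nS <- as.integer(config@nSamples)
        locs <- paste0("Location", seq_len(config@nLocations))
        types <- paste0("type", seq_len(config@nSiteTypesPerLocation))
        sampleIds <- sprintf("S%02d", seq_len(nS))
        meta <- data.frame(
            sample_id = sampleIds,
            location = locs[(seq_len(nS) - 1L) %% length(locs) + 1L],
            site_type = types[((seq_len(nS) - 1L) %/% length(locs)) %%
                                  length(types) + 1L],
            substrate = rep_len(c("moss", "water", "biofilm", "swab"), nS),
            pH = round(runif(nS, 3, 7), 1),
            stringsAsFactors = FALSE)
        rownames(meta) <- sampleIds

        # heavy-tailed base abundances; habitat restriction for a fraction
        base <- rlnorm(nF, meanlog = 0, sdlog = config@abundanceSigma)
        names(base) <- otuIdsF
        specific <- runif(nF) < config@specificityFraction
        habitat <- lapply(seq_len(nF), function(i)
            if (specific[i]) sample(locs, 1L) else locs)
        names(habitat) <- otuIdsF

        nFail <- round(config@failedSampleFraction * nS)
        failedIdx <- if (nFail > 0) sort(sample(nS, nFail)) else integer()
        depths <- round(10 ^ runif(nS, config@depthLog10Range[1],
                                   config@depthLog10Range[2]))
        depths[failedIdx] <- round(runif(length(failedIdx), 50, 499))

        clean <- matrix(0L, nOtu, nS, dimnames = list(allIds, sampleIds))
        for (j in seq_len(nS)) {
            mask <- vapply(habitat, function(h) meta$location[j] %in% h,
                           logical(1))
            p <- base * mask
            # a location no OTU can occupy yields an empty library
            if (sum(p) > 0)
                clean[seq_len(nF), j] <-
                    as.integer(rmultinom(1, depths[j], p))
        }
        if (nC > 0) {
            for (c_id in otuIdsC) {
                hit <- sample(nS, max(1L, rbinom(1, nS, 0.3)))
                w <- rlnorm(1, 0, 1)
                for (j in hit)
                    clean[c_id, j] <- clean[c_id, j] +
                        as.integer(stats::rpois(1, 0.005 * depths[j] * w))
            }
        }

        # index switching: each read independently jumps to a uniform other
        # sample; record every (otu, from, to) packet with its read count
        corrupted <- clean
        moves <- list()
        if (config@switchRate > 0 && nS > 1) {
            for (i in seq_len(nOtu)) for (j in seq_len(nS)) {
                n <- clean[i, j]
                if (n == 0) next
                mv <- rbinom(1, n, config@switchRate)
                if (mv == 0) next
                dest <- as.integer(rmultinom(1, mv, rep(1, nS - 1)))
                others <- seq_len(nS)[-j]
                corrupted[i, j] <- corrupted[i, j] - mv
                for (k in seq_along(others)) {
                    if (dest[k] == 0) next
                    corrupted[i, others[k]] <- corrupted[i, others[k]] +
                        dest[k]
                    moves[[length(moves) + 1L]] <- data.frame(
                        otu_id = allIds[i], from_sample = sampleIds[j],
                        to_sample = sampleIds[others[k]], reads = dest[k],
                        stringsAsFactors = FALSE)
                }
            }
        }
        switched <- if (length(moves)) do.call(rbind, moves) else
            data.frame(otu_id = character(), from_sample = character(),
                       to_sample = character(), reads = integer(),
                       stringsAsFactors = FALSE)

        # a library is "failed" as observed: fewer than 500 reads after
        # corruption (index switching can nudge a borderline library over
        # the floor, in which case it is not observably failed)
        observedFailed <- sampleIds[colSums(corrupted) < 500]
        truth <- new("SimTruth",
                     cleanTable = OtuTable(clean, meta),
                     contaminantOtuIds = otuIdsC,
                     switchedCells = switched,
                     failedSampleIds = observedFailed,
                     chimeraSeqIds = names(seqs$chimeras),
                     chimeraInfo = seqs$chimeraInfo,
                     tree = tree,
                     habitatMap = habitat)
        list(table = OtuTable(corrupted, meta), truth = truth,
             sequences = c(seqs$sequences, seqs$chimeras))
    })
}
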