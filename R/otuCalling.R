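#' Dereplicated amplicon sequences
#'
#' One entry per distinct sequence with per-sample read counts, sorted by
#' total count descending (ties by sequence, C-locale lexicographic).
#'
#' @slot sequences named character vector (names are `seq` ids, values
#'   uppercase ACGT strings).
#' @slot counts integer matrix, sequences x samples, rownames matching
#'   `names(sequences)`.
#' @export
setClass("DerepSet",
         representation(sequences = "character", counts = "matrix"))

setValidity("DerepSet", function(object) {
    if (length(object@sequences) == 0 && nrow(object@counts) == 0)
        return(TRUE)
    if (!identical(names(object@sequences), rownames(object@counts)))
        return("sequence names and count rownames must match")
    if (length(object@sequences) && any(rowSums(object@counts) < 1))
        return("every dereplicated sequence needs at least one read")
    if (length(grep("[^ACGT]", object@sequences)))
        return("sequences must be uppercase ACGT")
    TRUE
})

setMethod("show", "DerepSet", function(object) {
    cat(sprintf("DerepSet: %d distinct sequences, %d samples, %d reads\n",
                length(object@sequences), ncol(object@counts),
                sum(object@counts)))
})

#' Swarm-style OTU clusters over a dereplicated set
#'
#' Clusters are ordered by total read count descending (ties by seed
#' sequence); each cluster's seed is its most abundant member.
#'
#' @slot derep the underlying [DerepSet-class] (never subset).
#' @slot clusterIds character, one id per cluster.
#' @slot seedIdx integer index of each cluster's seed in `derep`.
#' @slot members list of integer vectors indexing `derep`.
#' @slot totals numeric total reads per cluster.
#' @export
setClass("OtuClusterSet", representation(
    derep = "DerepSet", clusterIds = "character", seedIdx = "integer",
    members = "list", totals = "numeric"))

setValidity("OtuClusterSet", function(object) {
    k <- length(object@clusterIds)
    if (length(object@seedIdx) != k || length(object@members) != k ||
        length(object@totals) != k)
        return("cluster slots must have equal length")
    for (i in seq_len(k))
        if (!(object@seedIdx[i] %in% object@members[[i]]))
            return("each seed must be a member of its cluster")
    TRUE
})

setMethod("show", "OtuClusterSet", function(object) {
    cat(sprintf("OtuClusterSet: %d clusters over %d sequences (%s reads)\n",
                length(object@clusterIds), length(object@derep@sequences),
                format(sum(object@totals), big.mark = ",")))
})

#' @rdname OtuClusterSet-class
#' @param x an `OtuClusterSet`.
#' @export
clusterIds <- function(x) x@clusterIds

#' @rdname OtuClusterSet-class
#' @export
clusterTotals <- function(x) setNames(x@totals, x@clusterIds)

#' @rdname OtuClusterSet-class
#' @export
clusterSeeds <- function(x)
    setNames(unname(x@derep@sequences[x@seedIdx]), x@clusterIds)

subsetClusters <- function(x, idx) {
    new("OtuClusterSet", derep = x@derep, clusterIds = x@clusterIds[idx],
        seedIdx = x@seedIdx[idx], members = x@members[idx],
        totals = x@totals[idx])
}

#' Dereplicate labelled reads
#'
#' Collapses a multiset of sample-labelled reads to one record per distinct
#' sequence with per-sample counts. Output is sorted by total count
#' descending, ties broken by sequence (lexicographic), making downstream
#' clustering deterministic.
#'
#' @param reads a `data.frame` with columns `sequence`, `sample` and
#'   optionally `count` (default 1 per row; rows may carry pre-aggregated
#'   counts, e.g. from `;size=` FASTA annotations).
#' @return a [DerepSet-class].
#' @examples
#' d <- dereplicate(data.frame(sequence = c("AAA", "AAA", "AAT"),
#'                             sample = c("s1", "s2", "s1")))
#' sum(d@counts)
#' @export
dereplicate <- function(reads) {
    stopifnot(is.data.frame(reads),
              all(c("sequence", "sample") %in% names(reads)))
    if (!nrow(reads)) {
        return(new("DerepSet", sequences = setNames(character(), character()),
                   counts = matrix(0L, 0, 0,
                                   dimnames = list(character(), character()))))
    }
    if (is.null(reads$count)) reads$count <- 1L
    if (any(reads$count < 1)) stop("read counts must be >= 1")
    assertAcgt(unique(reads$sequence), "reads")
    samples <- unique(as.character(reads$sample))
    agg <- stats::aggregate(count ~ sequence + sample, data = reads, FUN = sum)
    seqs <- unique(agg$sequence)
    m <- matrix(0L, length(seqs), length(samples),
                dimnames = list(seqs, samples))
    m[cbind(match(agg$sequence, seqs), match(agg$sample, samples))] <-
        as.integer(agg$count)
    tot <- rowSums(m)
    ord <- order(-tot, seqs, method = "radix")
    m <- m[ord, , drop = FALSE]
    ids <- sprintf("seq%d", seq_len(nrow(m)))
    sequences <- setNames(rownames(m), ids)
    rownames(m) <- ids
    new("DerepSet", sequences = sequences, counts = m)
}

#' Levenshtein edit distance between two sequences
#'
#' Unit-cost insertions, deletions and substitutions.
#'
#' @param a,b ACGT strings.
#' @return integer distance.
#' @examples
#' editDistance("ACGT", "ACT")
#' @export
editDistance <- function(a, b) {
    as.integer(adist(a, b)[1, 1])
}

#' Cluster dereplicated sequences by iterative seed growth
#'
#' Swarm-style single-linkage clustering at a small edit-distance radius:
#' the most abundant unassigned sequence seeds a cluster, which then grows
#' by repeatedly attaching any unassigned sequence within edit distance
#' `d` of any current member (frontier expansion) until no sequence can be
#' attached; the next seed starts a new cluster. With greedy frontier
#' expansion the resulting partition equals the connected components of the
#' distance-`d` graph, with each cluster seeded at its abundance maximum.
#'
#' @param derep a [DerepSet-class], sorted as produced by [dereplicate()].
#' @param d edit-distance radius (default 1, the swarm default).
#' @return an [OtuClusterSet-class]; clusters ordered by total reads
#'   descending, ids `OTU1`, `OTU2`, ...
#' @examples
#' d <- dereplicate(data.frame(
#'     sequence = c(rep("AAAA", 5), "AAAT", "GGGG"),
#'     sample = "s1"))
#' cl <- swarmCluster(d)
#' clusterTotals(cl)
#' @export
swarmCluster <- function(derep, d = 1) {
    stopifnot(is(derep, "DerepSet"))
    if (d < 0) stop("d must be >= 0")
    n <- length(derep@sequences)
    if (n == 0)
        return(new("OtuClusterSet", derep = derep, clusterIds = character(),
                   seedIdx = integer(), members = list(), totals = numeric()))
    tot <- rowSums(derep@counts)
    if (is.unsorted(-tot)) stop("derep must be sorted by total count")
    dm <- adist(derep@sequences)
    adj <- dm <= d
    assigned <- rep(FALSE, n)
    members <- list(); seedIdx <- integer()
    while (any(!assigned)) {
        seed <- which(!assigned)[1L]          # most abundant unassigned
        comp <- seed
        frontier <- seed
        assigned[seed] <- TRUE
        while (length(frontier)) {
            hits <- unname(which(!assigned &
                          colSums(adj[frontier, , drop = FALSE]) > 0))
            assigned[hits] <- TRUE
            comp <- c(comp, hits)
            frontier <- hits
        }
        members[[length(members) + 1L]] <- sort(comp)
        seedIdx <- c(seedIdx, seed)
    }
    totals <- vapply(members, function(m) sum(tot[m]), numeric(1))
    ord <- order(-totals, derep@sequences[seedIdx], method = "radix")
    new("OtuClusterSet", derep = derep,
        clusterIds = sprintf("OTU%d", seq_along(ord)),
        seedIdx = seedIdx[ord], members = members[ord],
        totals = totals[ord])
}

#' Remove single-read OTUs
#'
#' OTU clusters whose total read count is exactly one are moved to the
#' removed set.
#'
#' @param clusters an [OtuClusterSet-class].
#' @return list with `kept` and `removed` cluster sets.
#' @export
removeSingletonOtus <- function(clusters) {
    stopifnot(is(clusters, "OtuClusterSet"))
    single <- clusters@totals == 1
    list(kept = subsetClusters(clusters, !single),
         removed = subsetClusters(clusters, single))
}

#' Global alignment identity
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a
#' linear gap penalty of -1; identity is the number of matched columns
#' divided by the total number of alignment columns, gap columns included
#' (a conservative denominator). Among score-optimal alignments the one
#' with the most matches, then the fewest columns, is used, which makes the
#' value deterministic.
#'
#' @param a,b non-empty ACGT strings.
#' @return identity in [0, 1].
#' @examples
#' globalIdentity("ACGT", "ACGT")   # 1
#' globalIdentity("AAAA", "TTTT")   # 0
#' @export
globalIdentity <- function(a, b) {
    stopifnot(nzchar(a), nzchar(b))
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    n <- length(x); m <- length(y)
    # DP over (score, matches, -columns), lexicographically maximised
    S <- matrix(0, n + 1, m + 1)   # best score
    M <- matrix(0, n + 1, m + 1)   # matches under best score
    C <- matrix(0, n + 1, m + 1)   # columns under best (score, matches)
    S[1, ] <- -(0:m); C[1, ] <- 0:m
    S[, 1] <- -(0:n); C[, 1] <- 0:n
    for (i in seq_len(n)) {
        mt <- x[i] == y                      # match indicator vs all of y
        for (j in seq_len(m)) {
            sd <- S[i, j] + (x[i] == y[j])
            md <- M[i, j] + (x[i] == y[j])
            cd <- C[i, j] + 1
            su <- S[i, j + 1] - 1; mu <- M[i, j + 1]; cu <- C[i, j + 1] + 1
            sl <- S[i + 1, j] - 1; ml <- M[i + 1, j]; cl <- C[i + 1, j] + 1
            # pick max by (score, matches, -columns)
            bs <- sd; bm <- md; bc <- cd
            if (su > bs || (su == bs && (mu > bm || (mu == bm && cu < bc)))) {
                bs <- su; bm <- mu; bc <- cu
            }
            if (sl > bs || (sl == bs && (ml > bm || (ml == bm && cl < bc)))) {
                bs <- sl; bm <- ml; bc <- cl
            }
            S[i + 1, j + 1] <- bs; M[i + 1, j + 1] <- bm; C[i + 1, j + 1] <- bc
        }
    }
    M[n + 1, m + 1] / C[n + 1, m + 1]
}

# positionwise segment identity helpers used by flagChimeras; sequences are
# compared in amplicon coordinates (prefix left-anchored, suffix
# right-anchored), appropriate for fixed-length amplicons
prefixMatches <- function(s, p) {
    xs <- strsplit(s, "")[[1]]; xp <- strsplit(p, "")[[1]]
    L <- length(xs); Lp <- length(xp)
    k <- min(L, Lp)
    eq <- c(xs[seq_len(k)] == xp[seq_len(k)], rep(FALSE, L - k))
    cumsum(eq)
}

suffixMatches <- function(s, p) {
    xs <- strsplit(s, "")[[1]]; xp <- strsplit(p, "")[[1]]
    L <- length(xs); Lp <- length(xp)
    k <- min(L, Lp)
    eq <- c(rep(FALSE, L - k), rev(rev(xs)[seq_len(k)] == rev(xp)[seq_len(k)]))
    rev(cumsum(rev(eq)))       # matches of s[j..L] vs right-anchored p
}

#' Flag putative chimeric OTUs
#'
#' A transparent two-parent breakpoint test: a cluster seed S is flagged as
#' chimeric iff there exist two clusters A and B, each with at least twice
#' S's total abundance, and a breakpoint k such that S's prefix up to k
#' matches A's seed and S's suffix from k matches B's seed, each at >= 99%
#' positionwise identity with each segment covering at least 20% of S's
#' length, while S matches neither parent alone at >= 99% over its full
#' length (exact copies of a parent are never flagged).
#'
#' @param clusters an [OtuClusterSet-class], ordered by abundance.
#' @param minFold minimum parent/candidate abundance ratio (default 2).
#' @param segIdentity per-segment identity threshold (default 0.99).
#' @param minSegFrac minimum segment fraction of the candidate length
#'   (default 0.2).
#' @return character vector of flagged cluster ids.
#' @export
flagChimeras <- function(clusters, minFold = 2, segIdentity = 0.99,
                         minSegFrac = 0.2) {
    stopifnot(is(clusters, "OtuClusterSet"))
    k <- length(clusters@clusterIds)
    if (k < 3) return(character())
    seeds <- clusterSeeds(clusters)
    tot <- clusters@totals
    flagged <- character()
    for (s in seq_len(k)) {
        parents <- which(tot >= minFold * tot[s])
        parents <- setdiff(parents, s)
        if (length(parents) < 2) next
        S <- seeds[[s]]
        L <- nchar(S)
        lo <- ceiling(minSegFrac * L); hi <- floor((1 - minSegFrac) * L)
        if (lo > hi) next
        # skip candidates that are essentially a single parent
        full <- vapply(parents, function(p)
            sum(strsplit(S, "")[[1]] ==
                strsplit(substr(seeds[[p]], 1, L), "")[[1]][seq_len(L)],
                na.rm = TRUE) / L, numeric(1))
        live <- parents[full < segIdentity]
        if (length(live) < 2) next
        pref <- lapply(live, function(p) prefixMatches(S, seeds[[p]]))
        suf <- lapply(live, function(p) suffixMatches(S, seeds[[p]]))
        ks <- lo:hi
        hit <- FALSE
        for (ai in seq_along(live)) {
            prefOK <- pref[[ai]][ks] >= segIdentity * ks
            if (!any(prefOK)) next
            for (bi in seq_along(live)) {
                if (bi == ai) next
                sufOK <- suf[[bi]][ks + 1L] >= segIdentity * (L - ks)
                if (any(prefOK & sufOK)) { hit <- TRUE; break }
            }
            if (hit) break
        }
        if (hit) flagged <- c(flagged, clusters@clusterIds[s])
    }
    flagged
}

#' Remove OTUs highly divergent from the most abundant OTU
#'
#' The seed of the most abundant cluster is the reference; any cluster whose
#' seed aligns to it with [globalIdentity()] strictly below `minIdentity`
#' is removed (the reference itself is always kept). This drops highly
#' divergent off-target amplicons.
#'
#' @param clusters an [OtuClusterSet-class] with at least one cluster.
#' @param minIdentity keep threshold (default 0.65; removal is strict `<`).
#' @return list with `kept`, `removed` and `identities` (named numeric).
#' @export
divergenceFilter <- function(clusters, minIdentity = 0.65) {
    stopifnot(is(clusters, "OtuClusterSet"))
    if (!length(clusters@clusterIds)) stop("no clusters to filter")
    seeds <- clusterSeeds(clusters)
    ref <- seeds[[1L]]
    idy <- vapply(seeds, function(s) globalIdentity(s, ref), numeric(1))
    keep <- idy >= minIdentity
    keep[1L] <- TRUE
    list(kept = subsetClusters(clusters, keep),
         removed = subsetClusters(clusters, !keep),
         identities = setNames(idy, clusters@clusterIds))
}

#' Build an OTU table from clusters
#'
#' Cell (otu, sample) is the sum of the member sequences' per-sample counts.
#'
#' @param clusters an [OtuClusterSet-class].
#' @param samples sample ids for the columns; defaults to the samples seen
#'   at dereplication. Unseen samples get zero columns.
#' @return an [OtuTable-class] (rows in cluster order).
#' @export
buildOtuTable <- function(clusters, samples = NULL) {
    stopifnot(is(clusters, "OtuClusterSet"))
    if (is.null(samples)) samples <- colnames(clusters@derep@counts)
    k <- length(clusters@clusterIds)
    m <- matrix(0L, k, length(samples),
                dimnames = list(clusters@clusterIds, samples))
    seen <- intersect(samples, colnames(clusters@derep@counts))
    for (i in seq_len(k)) {
        cs <- colSums(clusters@derep@counts[clusters@members[[i]], seen,
                                            drop = FALSE])
        m[i, seen] <- as.integer(cs)
    }
    OtuTable(m)
}

#' Call OTUs from labelled reads
#'
#' Composes the full calling stage: [dereplicate()], [swarmCluster()],
#' [removeSingletonOtus()], [flagChimeras()] and [divergenceFilter()],
#' then builds the OTU table from the surviving clusters.
#'
#' @param reads `data.frame` as for [dereplicate()].
#' @param d clustering radius (default 1).
#' @param minIdentity divergence-filter threshold (default 0.65).
#' @return list with `table` ([OtuTable-class]), `clusters` (kept
#'   [OtuClusterSet-class]) and `log` (`data.frame` of removed/flagged
#'   cluster ids with reasons).
#' @export
callOtus <- function(reads, d = 1, minIdentity = 0.65) {
    derep <- dereplicate(reads)
    cl <- swarmCluster(derep, d = d)
    logRows <- list()
    sg <- removeSingletonOtus(cl)
    for (id in sg$removed@clusterIds)
        logRows[[length(logRows) + 1L]] <-
            data.frame(id = id, reason = "singleton",
                       stringsAsFactors = FALSE)
    chim <- flagChimeras(sg$kept)
    keepIdx <- !(sg$kept@clusterIds %in% chim)
    for (id in chim)
        logRows[[length(logRows) + 1L]] <-
            data.frame(id = id, reason = "chimera", stringsAsFactors = FALSE)
    noChim <- subsetClusters(sg$kept, keepIdx)
    dv <- if (length(noChim@clusterIds))
        divergenceFilter(noChim, minIdentity = minIdentity)
    else list(kept = noChim, removed = noChim)
    for (id in dv$removed@clusterIds)
        logRows[[length(logRows) + 1L]] <-
            data.frame(id = id, reason = "divergent",
                       stringsAsFactors = FALSE)
    log <- if (length(logRows)) do.call(rbind, logRows) else
        data.frame(id = character(), reason = character(),
                   stringsAsFactors = FALSE)
    list(table = buildOtuTable(dv$kept), clusters = dv$kept, log = log)
}
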