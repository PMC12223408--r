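test_that("dereplicate aggregates per sample and sorts deterministically", {
    d <- dereplicate(data.frame(sequence = c("AAA", "AAA", "AAT"),
                                sample = c("s1", "s2", "s1")))
    expect_length(d@sequences, 2L)
    expect_identical(unname(d@sequences[1]), "AAA")   # most abundant first
    expect_equal(sum(d@counts["seq1", ]), 2)
    expect_equal(unname(d@counts["seq1", c("s1", "s2")]), c(1L, 1L))

    empty <- dereplicate(data.frame(sequence = character(),
                                    sample = character()))
    expect_length(empty@sequences, 0L)

    withr::local_seed(1)
    reads <- data.frame(
        sequence = sample(c("ACGT", "ACGA", "TTTT", "GGGG"), 1000, TRUE),
        sample = sample(c("a", "b", "c"), 1000, TRUE))
    expect_equal(sum(dereplicate(reads)@counts), 1000)

    expect_error(dereplicate(data.frame(sequence = "ACGN", sample = "s1")),
                 "non-ACGT")
})

test_that("editDistance agrees with the recursive definition", {
    expect_identical(editDistance("ACGT", "ACGT"), 0L)
    expect_identical(editDistance("ACGT", "ACT"), 1L)
    withr::local_seed(42)
    alpha <- c("A", "C", "G", "T")
    for (i in 1:25) {
        a <- paste(sample(alpha, sample(1:9, 1), TRUE), collapse = "")
        b <- paste(sample(alpha, sample(1:9, 1), TRUE), collapse = "")
        expect_identical(editDistance(a, b), as.integer(
            oracleEditDistance(a, b)))
    }
})

test_that("swarm clustering chains single-edit neighbours through a seed", {
    # A (10 reads) -- B = A+1 edit (3 reads) -- C = B+1 edit (1 read):
    # the chain rule pulls all three into one cluster seeded at A
    reads <- data.frame(sequence = c("AAAAAAAA", "AAAAAAAT", "AAAAAATT"),
                        sample = "s1", count = c(10L, 3L, 1L))
    cl <- swarmCluster(dereplicate(reads))
    expect_length(clusterIds(cl), 1L)
    expect_identical(unname(clusterSeeds(cl)[1]), "AAAAAAAA")
    expect_equal(unname(clusterTotals(cl)[1]), 14)

    # three substitutions apart: two singleton-sequence clusters
    far <- dereplicate(data.frame(sequence = c("AAAAAAAA", "AAAAATTT"),
                                  sample = "s1", count = c(5L, 2L)))
    expect_length(clusterIds(swarmCluster(far)), 2L)
})

test_that("swarm clustering equals the connected-components oracle", {
    for (s in 1:20) {
        reads <- randomReadSet(nBase = 6, nVar = 24, len = 10, seed = s)
        derep <- dereplicate(reads)
        cl <- swarmCluster(derep, d = 1)
        oc <- oracleComponents(derep@sequences, rowSums(derep@counts))
        # same partition
        got <- lapply(cl@members, identity)
        want <- lapply(oc, `[[`, "members")
        expect_setequal(vapply(got, paste, "", collapse = ","),
                        vapply(want, paste, "", collapse = ","))
        # seeds are per-component abundance maxima
        wantSeeds <- sort(vapply(oc, `[[`, 0L, "seed"))
        expect_identical(sort(cl@seedIdx), wantSeeds)
        # partition: every sequence in exactly one cluster
        expect_identical(sort(unlist(cl@members)),
                         seq_along(derep@sequences))
    }
})

test_that("globalIdentity matches exhaustive alignment enumeration", {
    expect_equal(globalIdentity("ACGTACGT", "ACGTACGT"), 1.0)
    expect_equal(globalIdentity("AAAA", "TTTT"), 0.0)
    withr::local_seed(7)
    alpha <- c("A", "C", "G", "T")
    for (i in 1:15) {
        a <- paste(sample(alpha, sample(2:7, 1), TRUE), collapse = "")
        b <- paste(sample(alpha, sample(2:7, 1), TRUE), collapse = "")
        expect_equal(globalIdentity(a, b), oracleGlobalIdentity(a, b),
                     info = paste(a, b))
    }
})

test_that("singleton OTU removal partitions clusters at one read", {
    reads <- data.frame(sequence = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                        sample = "s1", count = c(5L, 2L, 1L))
    cl <- swarmCluster(dereplicate(reads))
    parts <- removeSingletonOtus(cl)
    expect_length(clusterIds(parts$kept), 2L)     # totals 5 and 2 kept
    expect_length(clusterIds(parts$removed), 1L)  # total 1 removed
    expect_equal(length(clusterIds(parts$kept)) +
                     length(clusterIds(parts$removed)),
                 length(clusterIds(cl)))
})

test_that("constructed chimeras are flagged, parent copies are not", {
    withr::local_seed(11)
    alpha <- c("A", "C", "G", "T")
    a <- paste(sample(alpha, 100, TRUE), collapse = "")
    b <- paste(sample(alpha, 100, TRUE), collapse = "")
    chim <- paste0(substr(a, 1, 50), substr(b, 51, 100))
    reads <- data.frame(sequence = c(a, b, chim), sample = "s1",
                        count = c(100L, 80L, 10L))
    cl <- swarmCluster(dereplicate(reads))
    flagged <- flagChimeras(cl)
    seeds <- clusterSeeds(cl)
    expect_identical(unname(seeds[flagged]), chim)

    # an abundant copy of one parent matches it full length: never flagged
    reads2 <- data.frame(sequence = c(a, b, a), sample = c("s1", "s1", "s2"),
                         count = c(100L, 80L, 10L))
    cl2 <- swarmCluster(dereplicate(reads2))
    expect_length(flagChimeras(cl2), 0L)
})

test_that("chimera recall on simulated communities is at least 0.9", {
    hit <- 0; tot <- 0
    for (s in 1:20) {
        tr <- simulateTree(20, seed = s)
        sq <- simulateSequences(tr, 200, subsRate = 0.2, chimeraRate = 0.2,
                                seed = s + 100)
        reads <- rbind(
            data.frame(sequence = unname(sq$sequences), sample = "s1",
                       count = 100L),
            data.frame(sequence = unname(sq$chimeras), sample = "s1",
                       count = 10L))
        cl <- swarmCluster(dereplicate(reads))
        flagged <- flagChimeras(cl)
        seeds <- clusterSeeds(cl)
        chimClusters <- names(seeds)[seeds %in% sq$chimeras]
        tot <- tot + length(chimClusters)
        hit <- hit + sum(chimClusters %in% flagged)
    }
    expect_gte(hit / tot, 0.9)
})

test_that("divergence filter drops seeds below 65% identity, strictly", {
    withr::local_seed(13)
    ref <- paste(rep("ACGT", 25), collapse = "")     # 100 bp
    mutate <- function(s, n) {
        x <- strsplit(s, "")[[1]]
        pos <- sample(100, n)
        x[pos] <- vapply(x[pos], function(ch)
            sample(setdiff(c("A", "C", "G", "T"), ch), 1), "")
        paste(x, collapse = "")
    }
    at65 <- mutate(ref, 35)
    at64 <- mutate(ref, 36)
    # substitution-only variants: alignment identity >= positionwise floor
    reads <- data.frame(sequence = c(ref, at65, at64), sample = "s1",
                        count = c(50L, 10L, 10L))
    cl <- swarmCluster(dereplicate(reads))
    dv <- divergenceFilter(cl)
    ids <- dv$identities
    seeds <- clusterSeeds(cl)
    expect_equal(unname(ids[names(seeds)[seeds == ref]]), 1.0)
    kept <- clusterSeeds(dv$kept)
    if (unname(ids[names(seeds)[seeds == at64]]) < 0.65)
        expect_false(at64 %in% kept)
    expect_true(ref %in% kept)                       # reference always kept

    # keep is >=, removal strictly below the threshold: a pair at exactly
    # identity 0.5 survives a 0.5 threshold
    pair <- data.frame(sequence = c("AAAAAAAA", "AAAATTTT"), sample = "s1",
                       count = c(9L, 4L))
    clp <- swarmCluster(dereplicate(pair))
    expect_equal(unname(divergenceFilter(clp)$identities[2]), 0.5)
    expect_length(clusterIds(divergenceFilter(clp, 0.5)$kept), 2L)
    expect_length(clusterIds(divergenceFilter(clp, 0.51)$kept), 1L)

    # a random (unrelated) contaminant sits far below 65% nearly always
    drops <- vapply(1:20, function(s) {
        withr::local_seed(s)
        rnd <- paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                     collapse = "")
        r <- data.frame(sequence = c(ref, rnd), sample = "s1",
                        count = c(50L, 5L))
        d <- divergenceFilter(swarmCluster(dereplicate(r)))
        !(rnd %in% clusterSeeds(d$kept))
    }, logical(1))
    expect_gte(mean(drops), 0.95)
})

test_that("the OTU table recounts every read of its clusters", {
    one <- dereplicate(data.frame(sequence = "ACGTACGT", sample = "s1",
                                  count = 5L))
    t1 <- buildOtuTable(swarmCluster(one))
    expect_identical(dim(otuCounts(t1)), c(1L, 1L))
    expect_equal(sum(otuCounts(t1)), 5)

    reads <- randomReadSet(5, 15, len = 9, seed = 77)
    derep <- dereplicate(reads)
    cl <- swarmCluster(derep)
    tab <- buildOtuTable(cl)
    expect_equal(unname(sampleDepths(tab)[colnames(derep@counts)]),
                 unname(colSums(derep@counts)))
    expect_equal(sum(otuCounts(tab)), sum(reads$count))

    emptyCl <- swarmCluster(dereplicate(
        data.frame(sequence = character(), sample = character())))
    t0 <- buildOtuTable(emptyCl, samples = c("sA", "sB"))
    expect_identical(dim(otuCounts(t0)), c(0L, 2L))
})

test_that("callOtus conserves reads between table and removal log", {
    withr::local_seed(5)
    tr <- simulateTree(12, seed = 5)
    sq <- simulateSequences(tr, 150, subsRate = 0.25, chimeraRate = 0.1,
                            seed = 6)
    reads <- rbind(
        data.frame(sequence = rep(unname(sq$sequences), each = 2),
                   sample = rep(c("s1", "s2"), 12),
                   count = rep(c(40L, 25L), 12)),
        data.frame(sequence = unname(sq$chimeras), sample = "s1",
                   count = 8L),
        data.frame(sequence = paste(sample(c("A", "C", "G", "T"), 150,
                                           TRUE), collapse = ""),
                   sample = "s2", count = 1L))   # a singleton
    res <- callOtus(reads)
    expect_s4_class(res$table, "OtuTable")
    expect_true(all(c("singleton") %in% res$log$reason))
    # reads in = reads in table + reads in removed clusters
    derep <- dereplicate(reads)
    cl <- swarmCluster(derep)
    removedReads <- sum(clusterTotals(cl)[res$log$id])
    expect_equal(sum(otuCounts(res$table)) + removedReads,
                 sum(reads$count))
})
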