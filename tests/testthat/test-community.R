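test_that("relative abundance normalises every sample to 1", {
    one <- OtuTable(matrix(7L, 1, 1, dimnames = list("a", "s")))
    expect_equal(relativeAbundance(one)[1, 1], 1.0)

    m <- matrix(c(25L, 75L), 2, 1, dimnames = list(c("a", "b"), "s1"))
    expect_equal(unname(relativeAbundance(OtuTable(m))[, 1]), c(0.25, 0.75))

    r <- randomCountTable(12, 8, seed = 2, lambda = 30)
    r[, 1] <- r[, 1] + 1L   # guard against an all-zero column
    ra <- relativeAbundance(OtuTable(r))
    expect_true(all(abs(colSums(ra) - 1) < 1e-12))

    z <- matrix(c(5L, 0L), 1, 2, dimnames = list("a", c("ok", "empty")))
    expect_error(relativeAbundance(OtuTable(z)), "empty")
})

test_that("presence classes partition (0,1] with inclusive mid-range", {
    expect_equal(as.character(classifyPresence(0.10)), "rare")
    expect_equal(as.character(classifyPresence(0.25)), "intermediate")
    expect_equal(as.character(classifyPresence(0.75)), "intermediate")
    expect_equal(as.character(classifyPresence(0.90)), "dominant")
    withr::local_seed(3)
    x <- runif(200, 1e-6, 1)
    cls <- classifyPresence(x)
    expect_false(anyNA(cls))                     # exactly one class each
    expect_true(all(x[cls == "rare"] < 0.25))
    expect_true(all(x[cls == "dominant"] > 0.75))
    expect_true(all(x[cls == "intermediate"] >= 0.25 &
                        x[cls == "intermediate"] <= 0.75))
    expect_error(classifyPresence(0), "0, 1")
    expect_error(classifyPresence(1.2), "0, 1")
})

test_that("weighted UniFrac closed forms and errors", {
    tr <- ape::read.tree(text = "(A:1,B:1);")
    m <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
                dimnames = list(c("A", "B"), c("sA", "sB")))
    tab <- OtuTable(m)
    expect_equal(weightedUnifrac(tab, tr, normalized = FALSE)["sA", "sB"],
                 2.0)
    expect_equal(weightedUnifrac(tab, tr, normalized = TRUE)["sA", "sB"],
                 1.0)

    same <- OtuTable(matrix(c(3L, 7L, 6L, 14L), 2, 2,
                            dimnames = list(c("A", "B"), c("s1", "s2"))))
    D <- weightedUnifrac(same, tr)   # proportional columns: distance 0
    expect_equal(D["s1", "s2"], 0)

    bad <- OtuTable(matrix(1L, 1, 1, dimnames = list("Z", "s")))
    expect_error(weightedUnifrac(bad, tr), "missing from tree.*Z")
})

test_that("weighted UniFrac matches branch enumeration and phyloseq", {
    for (s in 1:25) {
        withr::local_seed(s)
        nTip <- sample(4:10, 1); nSamp <- sample(3:6, 1)
        tr <- ape::rtree(nTip)
        tr$tip.label <- paste0("t", seq_len(nTip))
        m <- matrix(rpois(nTip * nSamp, 15) + 1L, nTip, nSamp,
                    dimnames = list(tr$tip.label,
                                    paste0("s", seq_len(nSamp))))
        storage.mode(m) <- "integer"
        tab <- OtuTable(m)
        for (norm in c(TRUE, FALSE)) {
            got <- weightedUnifrac(tab, tr, normalized = norm)
            want <- oracleUnifrac(m, tr, normalized = norm)
            expect_lt(max(abs(got - want)), 1e-10)
        }
        ps <- phyloseq::phyloseq(
            phyloseq::otu_table(m, taxa_are_rows = TRUE),
            phyloseq::phy_tree(tr))
        ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = TRUE))
        got <- weightedUnifrac(tab, tr, normalized = TRUE)
        expect_lt(max(abs(got[rownames(ref), colnames(ref)] - ref)), 1e-8)
    }
})

test_that("weighted UniFrac is a metric, bounded and scale-invariant", {
    for (s in 1:10) {
        withr::local_seed(s)
        tr <- ape::rtree(8)
        tr$tip.label <- paste0("t", 1:8)
        m <- matrix(rpois(8 * 5, 10) + 1L, 8, 5,
                    dimnames = list(tr$tip.label, paste0("s", 1:5)))
        storage.mode(m) <- "integer"
        raw <- weightedUnifrac(OtuTable(m), tr, normalized = FALSE)
        expect_equal(raw, t(raw))
        expect_true(all(diag(raw) == 0))
        for (i in 1:5) for (j in 1:5) for (k in 1:5)
            expect_lte(raw[i, j], raw[i, k] + raw[k, j] + 1e-10)
        norm <- weightedUnifrac(OtuTable(m), tr, normalized = TRUE)
        expect_true(all(norm >= 0 & norm <= 1 + 1e-12))
        # multiplying one sample's counts leaves proportions unchanged
        m2 <- m; m2[, 3] <- m2[, 3] * 7L
        expect_equal(weightedUnifrac(OtuTable(m2), tr, normalized = FALSE),
                     raw)
    }
})

test_that("extra tree leaves are pruned, never silently kept", {
    withr::local_seed(4)
    tr <- ape::rtree(6)
    tr$tip.label <- paste0("t", 1:6)
    m <- matrix(rpois(4 * 3, 20) + 1L, 4, 3,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
    storage.mode(m) <- "integer"
    pruned <- ape::drop.tip(tr, c("t5", "t6"))
    expect_equal(weightedUnifrac(OtuTable(m), tr),
                 weightedUnifrac(OtuTable(m), pruned))
})

test_that("PCoA embeds Euclidean configurations isometrically", {
    # five points in the plane: exact reconstruction, two nonzero axes
    e <- randomEuclideanDist(5, 2, seed = 1)
    ord <- pcoaOrdination(e$dist)
    expect_equal(ncol(ordCoordinates(ord)), 2L)
    rec <- as.matrix(dist(ordCoordinates(ord)))
    expect_lt(max(abs(rec - e$dist)), 1e-8)
    expect_equal(sum(percentVariance(ord)), 100)

    # equilateral triangle: two equal positive eigenvalues, 50/50 split
    tri <- matrix(1, 3, 3) - diag(3)
    dimnames(tri) <- list(paste0("p", 1:3), paste0("p", 1:3))
    ordT <- pcoaOrdination(tri)
    expect_equal(percentVariance(ordT), c(50, 50))

    for (s in 1:10) {
        e <- randomEuclideanDist(sample(4:9, 1), sample(2:3, 1),
                                 seed = 100 + s)
        ord <- pcoaOrdination(e$dist)
        rec <- as.matrix(dist(ordCoordinates(ord)))
        expect_lt(max(abs(rec - e$dist)), 1e-8)
        expect_equal(sum(percentVariance(ord)), 100)
        # cross-check the embedding against classical MDS
        k <- ncol(ordCoordinates(ord))
        cmd <- stats::cmdscale(e$dist, k = k)
        expect_lt(max(abs(as.matrix(dist(cmd)) - rec)), 1e-8)
    }
    expect_error(pcoaOrdination(matrix(0, 2, 2)), "at least 3")
})

test_that("PCoA axes are deterministic in sign and eigenvalue order", {
    e <- randomEuclideanDist(7, 3, seed = 9)
    a <- pcoaOrdination(e$dist); b <- pcoaOrdination(e$dist)
    expect_identical(ordCoordinates(a), ordCoordinates(b))
    expect_true(all(diff(eigenvalues(a)) <= 1e-12))
    for (k in seq_len(ncol(ordCoordinates(a)))) {
        col <- ordCoordinates(a)[, k]
        expect_gt(col[which.max(abs(col))], 0)
    }
})

test_that("occupancy summary labels location-specific OTUs", {
    m <- matrix(c(5L, 0L, 0L, 0L,
                  3L, 4L, 2L, 1L), 2, 4, byrow = TRUE,
                dimnames = list(c("greenhouseOnly", "everywhere"),
                                paste0("s", 1:4)))
    meta <- data.frame(location = c("greenhouse", "bogA", "bogB", "bogC"),
                       site_type = c("pool", "open", "open", "edge"),
                       row.names = paste0("s", 1:4))
    occ <- occupancySummary(OtuTable(m, meta))
    g <- occ$otus[occ$otus$otu_id == "greenhouseOnly", ]
    expect_equal(g$label, "specific")
    expect_equal(g$locations, "greenhouse")
    e <- occ$otus[occ$otus$otu_id == "everywhere", ]
    expect_equal(e$label, "shared")
    expect_equal(e$occupancy, 4L)
    expect_equal(e$n_locations, 4L)
    expect_equal(occ$locationRichness[["greenhouse"]], 2L)

    expect_error(occupancySummary(OtuTable(m), meta[1:2, , drop = FALSE]),
                 "missing metadata")
})

test_that("clean fully-specific communities are labelled from the truth map", {
    sim <- simulateDataset(simConfig(nSamples = 12, nFreshwaterOtus = 20,
                                     nContaminantOtus = 0,
                                     specificityFraction = 1,
                                     switchRate = 0,
                                     failedSampleFraction = 0, seed = 17))
    tab <- cleanTable(sim$truth)
    keep <- otuTotals(tab) > 0
    occ <- occupancySummary(tab[names(keep)[keep], ])
    expect_true(all(occ$otus$label == "specific"))
    hm <- habitatMap(sim$truth)
    for (r in seq_len(nrow(occ$otus)))
        expect_equal(occ$otus$locations[r], hm[[occ$otus$otu_id[r]]])
})

test_that("topKFraction matches brute-force sort-and-sum", {
    m <- matrix(c(50L, 30L, 20L), 3, 1,
                dimnames = list(c("a", "b", "c"), "s1"))
    tab <- OtuTable(m)
    expect_equal(topKFraction(tab, 1)$fraction, 0.5)
    expect_equal(topKFraction(tab, 3)$fraction, 1.0)
    expect_error(topKFraction(tab, 4), "exceeds")

    for (s in 1:10) {
        r <- randomCountTable(12, 5, seed = s)
        tab <- OtuTable(r)
        k <- sample(1:12, 1)
        want <- sum(sort(rowSums(r), decreasing = TRUE)[1:k]) / sum(r)
        expect_equal(topKFraction(tab, k)$fraction, want)
    }
})

test_that("same-location samples are closer in UniFrac than cross-location", {
    pvals <- vapply(1:3, function(s) {
        sim <- simulateDataset(simConfig(seed = s))
        cur <- runCuration(sim$table,
                           flaggedOtus = contaminantOtuIds(sim$truth),
                           seed = s)
        D <- weightedUnifrac(cur$table, sim$truth@tree)
        loc <- SummarizedExperiment::colData(cur$table)$location
        stat <- function(lab) {
            same <- outer(lab, lab, "==") & upper.tri(D)
            diff <- outer(lab, lab, "!=") & upper.tri(D)
            mean(D[same]) - mean(D[diff])
        }
        obs <- stat(loc)
        withr::local_seed(1000 + s)
        perm <- vapply(1:499, function(i) stat(sample(loc)), numeric(1))
        (1 + sum(perm <= obs)) / 500
    }, numeric(1))
    expect_true(all(pvals < 0.01))
})
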