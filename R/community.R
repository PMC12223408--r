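#' Relative abundance matrix
#'
#' Divides each cell by its sample (column) total; every retained sample
#' must have at least one read.
#'
#' @param table an [OtuTable-class].
#' @return a numeric matrix whose columns sum to 1.
#' @export
relativeAbundance <- function(table) {
    stopifnot(is(table, "OtuTable"))
    m <- otuCounts(table)
    cs <- colSums(m)
    if (any(cs == 0))
        stop("sample(s) with zero reads: ",
             paste(colnames(m)[cs == 0], collapse = ", "))
    sweep(m, 2, cs, "/")
}

#' Classify per-sample OTU presences by relative abundance
#'
#' Presences are `"rare"` below 25% of a sample's reads, `"intermediate"`
#' between 25% and 75% (both endpoints inclusive) and `"dominant"` above
#' 75%. The three classes partition (0, 1]; zero fractions are absences,
#' not presences, and are rejected.
#'
#' @param fraction numeric vector of relative abundances in (0, 1].
#' @return factor with levels `rare`, `intermediate`, `dominant`.
#' @examples
#' classifyPresence(c(0.1, 0.25, 0.5, 0.75, 0.9))
#' @export
classifyPresence <- function(fraction) {
    if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction > 1))
        stop("fractions must lie in (0, 1]")
    cls <- ifelse(fraction < 0.25, "rare",
                  ifelse(fraction > 0.75, "dominant", "intermediate"))
    factor(cls, levels = c("rare", "intermediate", "dominant"))
}

#' Long-format abundance classification of a curated table
#'
#' Applies [classifyPresence()] to every nonzero cell.
#'
#' @param table an [OtuTable-class].
#' @return `data.frame` with columns `otu_id`, `sample_id`, `reads`,
#'   `fraction`, `class`.
#' @export
classifyTable <- function(table) {
    ra <- relativeAbundance(table)
    m <- otuCounts(table)
    nz <- which(m > 0, arr.ind = TRUE)
    out <- data.frame(otu_id = rownames(m)[nz[, 1]],
                      sample_id = colnames(m)[nz[, 2]],
                      reads = m[nz], fraction = ra[nz],
                      stringsAsFactors = FALSE)
    out$class <- classifyPresence(out$fraction)
    out[order(match(out$otu_id, rownames(m)),
              match(out$sample_id, colnames(m))), , drop = FALSE]
}

# proportion of each sample's reads descending through every branch:
# edges x samples matrix, computed by postorder accumulation
branchProportions <- function(tree, prop) {
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    acc <- matrix(0, nNode, ncol(prop))
    acc[seq_len(nTip), ] <- prop[tree$tip.label, , drop = FALSE]
    tr <- ape::reorder.phylo(tree, "postorder")
    for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
        acc[par, ] <- acc[par, ] + acc[chi, ]
    }
    # row e of the result corresponds to edge e of the *input* tree
    P <- acc[tree$edge[, 2], , drop = FALSE]
    colnames(P) <- colnames(prop)
    P
}

#' Weighted UniFrac distances between samples
#'
#' For two samples A and B, the raw weighted UniFrac distance is
#' \deqn{d(A,B) = \sum_i b_i \, |p_i(A) - p_i(B)|}{d(A,B) = sum_i b_i |p_i(A) - p_i(B)|}
#' summed over all branches i, where \eqn{b_i} is the branch length and
#' \eqn{p_i(X)} the fraction of sample X's reads descending from branch i.
#' The normalised variant divides by \eqn{\sum_i b_i (p_i(A) + p_i(B))},
#' bounding the distance in [0, 1]. Tree leaves not present in the table
#' are pruned automatically; table OTUs missing from the tree are an error.
#'
#' @param table an [OtuTable-class] with positive sample totals.
#' @param tree a rooted `phylo` with branch lengths whose tips cover the
#'   table's OTUs.
#' @param normalized use the bounded, proportion-normalised variant
#'   (default TRUE).
#' @return symmetric numeric matrix of distances with zero diagonal,
#'   dimnames = sample ids.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' m <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' weightedUnifrac(OtuTable(m), tr, normalized = FALSE)  # 2 off-diagonal
#' @export
weightedUnifrac <- function(table, tree, normalized = TRUE) {
    stopifnot(is(table, "OtuTable"), inherits(tree, "phylo"))
    miss <- setdiff(otuIds(table), tree$tip.label)
    if (length(miss))
        stop("table OTUs missing from tree: ", paste(miss, collapse = ", "))
    if (is.null(tree$edge.length))
        stop("tree must have branch lengths")
    extra <- setdiff(tree$tip.label, otuIds(table))
    if (length(extra)) tree <- ape::drop.tip(tree, extra)
    prop <- relativeAbundance(table)
    P <- branchProportions(tree, prop)
    b <- tree$edge.length
    n <- ncol(prop)
    D <- matrix(0, n, n, dimnames = list(colnames(prop), colnames(prop)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        num <- sum(b * abs(P[, i] - P[, j]))
        d <- if (normalized) {
            den <- sum(b * (P[, i] + P[, j]))
            if (den > 0) num / den else 0
        } else num
        D[i, j] <- D[j, i] <- d
    }
    D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of \eqn{-d^2/2} followed by a symmetric
#' eigendecomposition. Coordinates are returned for positive eigenvalues
#' only, scaled by the square root of the eigenvalue; negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as UniFrac) are
#' reported but excluded from the percent-variance denominator. Axis signs
#' are fixed so the largest-magnitude loading on each axis is positive,
#' making the embedding deterministic.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal (or a
#'   `dist` object), at least 3 samples.
#' @return an [OrdinationResult-class].
#' @examples
#' pts <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' rownames(pts) <- paste0("s", 1:4)
#' ord <- pcoaOrdination(as.matrix(dist(pts)))
#' percentVariance(ord)
#' @export
pcoaOrdination <- function(dist) {
    D <- as.matrix(dist)
    n <- nrow(D)
    if (n < 3) stop("need at least 3 samples")
    if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
        stop("dist must be symmetric with a zero diagonal")
    A <- -0.5 * D^2
    J <- diag(n) - matrix(1 / n, n, n)
    B <- J %*% A %*% J
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    ev <- eig$values
    tol <- 1e-8 * max(abs(ev), 1e-12)
    pos <- which(ev > tol)
    coords <- eig$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(ev[pos]), length(pos))
    for (k in seq_len(ncol(coords))) {
        top <- which.max(abs(coords[, k]))
        if (coords[top, k] < 0) coords[, k] <- -coords[, k]
    }
    rownames(coords) <- rownames(D)
    colnames(coords) <- paste0("PCo", seq_along(pos))
    pv <- 100 * ev[pos] / sum(ev[pos])
    if (length(pv)) pv <- pv / sum(pv) * 100
    new("OrdinationResult", coordinates = coords, eigenvalues = ev,
        percentVariance = pv)
}

#' Per-OTU occupancy and habitat-specificity summary
#'
#' For each OTU, the set of locations and site types where it was detected
#' (detection = at least one read after curation), its occupancy (number of
#' samples), and a `"specific"` (single location) versus `"shared"` label;
#' plus OTU richness per location.
#'
#' @param table a curated [OtuTable-class].
#' @param metadata `data.frame` with rownames (or `sample_id` column)
#'   covering all samples and columns `location` and `site_type`; defaults
#'   to the table's `colData`.
#' @return list with `otus` (`data.frame`: `otu_id`, `locations`,
#'   `site_types`, `occupancy`, `n_locations`, `label`) and
#'   `locationRichness` (named integer vector).
#' @export
occupancySummary <- function(table, metadata = NULL) {
    stopifnot(is(table, "OtuTable"))
    if (is.null(metadata))
        metadata <- as.data.frame(SummarizedExperiment::colData(table))
    if (!is.null(metadata$sample_id) &&
        is.null(rownames(metadata)) == FALSE &&
        !all(sampleIds(table) %in% rownames(metadata)))
        rownames(metadata) <- metadata$sample_id
    miss <- setdiff(sampleIds(table), rownames(metadata))
    if (length(miss))
        stop("samples missing metadata: ", paste(miss, collapse = ", "))
    if (!all(c("location", "site_type") %in% colnames(metadata)))
        stop("metadata needs 'location' and 'site_type' columns")
    metadata <- metadata[sampleIds(table), , drop = FALSE]
    m <- otuCounts(table)
    loc <- as.character(metadata$location)
    st <- as.character(metadata$site_type)
    rows <- lapply(seq_len(nrow(m)), function(i) {
        hit <- m[i, ] > 0
        locs <- sort(unique(loc[hit]))
        data.frame(otu_id = rownames(m)[i],
                   locations = paste(locs, collapse = ","),
                   site_types = paste(sort(unique(st[hit])), collapse = ","),
                   occupancy = sum(hit), n_locations = length(locs),
                   label = if (length(locs) == 1) "specific" else "shared",
                   stringsAsFactors = FALSE)
    })
    otus <- do.call(rbind, rows)
    rich <- vapply(sort(unique(loc)), function(L)
        sum(rowSums(m[, loc == L, drop = FALSE] > 0) > 0), integer(1))
    list(otus = otus, locationRichness = rich)
}

#' Fraction of reads held by the k most abundant OTUs
#'
#' @param table an [OtuTable-class].
#' @param k number of top OTUs (1 <= k <= number of OTUs).
#' @return list with `fraction` (of the grand total) and `otus` (the k ids,
#'   by descending total).
#' @examples
#' m <- matrix(c(50L, 30L, 20L), 3, 1,
#'             dimnames = list(c("a", "b", "c"), "s1"))
#' topKFraction(OtuTable(m), 1)$fraction  # 0.5
#' @export
topKFraction <- function(table, k) {
    stopifnot(is(table, "OtuTable"))
    k <- assertCount(k, "k")
    tot <- otuTotals(table)
    if (k > length(tot)) stop("k exceeds the number of OTUs")
    ord <- order(-tot, names(tot), method = "radix")
    top <- ord[seq_len(k)]
    list(fraction = sum(tot[top]) / sum(tot), otus = names(tot)[top])
}
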