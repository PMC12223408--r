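# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different algorithmic route from the package
# implementation it checks.

# Levenshtein distance by the textbook recursion (no DP sharing with the
# implementation, which delegates to utils::adist).
oracleEditDistance <- function(a, b) {
    rec <- function(i, j) {
        if (i == 0) return(j)
        if (j == 0) return(i)
        cost <- if (substr(a, i, i) == substr(b, j, j)) 0 else 1
        min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
    }
    rec(nchar(a), nchar(b))
}

# Global alignment identity by exhaustive enumeration of every monotone
# alignment (Delannoy paths), maximising (score, matches, -columns).
oracleGlobalIdentity <- function(a, b) {
    xa <- strsplit(a, "")[[1]]; xb <- strsplit(b, "")[[1]]
    best <- c(score = -Inf, matches = 0, cols = 0)
    rec <- function(i, j, score, matches, cols) {
        if (i > length(xa) && j > length(xb)) {
            better <- score > best["score"] ||
                (score == best["score"] && (matches > best["matches"] ||
                 (matches == best["matches"] && cols < best["cols"])))
            if (better) best <<- c(score = score, matches = matches,
                                   cols = cols)
            return(invisible())
        }
        if (i <= length(xa) && j <= length(xb)) {
            m <- xa[i] == xb[j]
            rec(i + 1, j + 1, score + m, matches + m, cols + 1)
        }
        if (i <= length(xa)) rec(i + 1, j, score - 1, matches, cols + 1)
        if (j <= length(xb)) rec(i, j + 1, score - 1, matches, cols + 1)
    }
    rec(1, 1, 0, 0, 0)
    unname(best["matches"] / best["cols"])
}

# Connected components of the edit-distance <= d graph, via igraph, with
# per-component abundance-maximal (then lexicographic) seeds.
oracleComponents <- function(seqs, totals, d = 1) {
    dm <- utils::adist(seqs)
    g <- igraph::graph_from_adjacency_matrix(dm <= d, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    lapply(unique(comp), function(k) {
        idx <- which(comp == k)
        seed <- idx[order(-totals[idx], seqs[idx], method = "radix")][1]
        list(members = sort(idx), seed = seed,
             total = sum(totals[idx]))
    })
}

# Weighted UniFrac by per-tip root-path enumeration: each tip contributes
# its proportion to every edge on its path to the root.
oracleUnifrac <- function(counts, tree, normalized = TRUE) {
    prop <- sweep(counts, 2, colSums(counts), "/")
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    parent <- integer(max(tree$edge))
    edgeOf <- integer(max(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
        parent[tree$edge[e, 2]] <- tree$edge[e, 1]
        edgeOf[tree$edge[e, 2]] <- e
    }
    P <- matrix(0, nrow(tree$edge), ncol(counts))
    for (t in seq_len(nTip)) {
        node <- t
        while (node != root) {
            P[edgeOf[node], ] <- P[edgeOf[node], ] +
                prop[tree$tip.label[t], ]
            node <- parent[node]
        }
    }
    n <- ncol(counts)
    D <- matrix(0, n, n, dimnames = list(colnames(counts),
                                         colnames(counts)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        num <- sum(tree$edge.length * abs(P[, i] - P[, j]))
        D[i, j] <- D[j, i] <- if (normalized) {
            den <- sum(tree$edge.length * (P[, i] + P[, j]))
            if (den > 0) num / den else 0
        } else num
    }
    D
}

# Unrarefied filter by naive repeated full sweeps on a raw matrix.
oracleFixpoint <- function(m, minSample = 500, minOtu = 100, minOcc = 2) {
    repeat {
        before <- dim(m)
        m <- m[, colSums(m) >= minSample, drop = FALSE]
        keep <- rowSums(m) >= minOtu & rowSums(m > 0) >= minOcc
        m <- m[keep, , drop = FALSE]
        if (identical(dim(m), before)) return(m)
    }
}

# Random read set with planted clusters: base sequences plus 1-edit
# variants, random counts.
randomReadSet <- function(nBase, nVar, len = 10, seed) {
    withr::local_seed(seed)
    alpha <- c("A", "C", "G", "T")
    bases <- replicate(nBase, paste(sample(alpha, len, TRUE), collapse = ""))
    seqs <- bases
    for (v in seq_len(nVar)) {
        b <- sample(bases, 1)
        pos <- sample(len, 1)
        substr(b, pos, pos) <- sample(alpha, 1)
        seqs <- c(seqs, b)
    }
    seqs <- unique(seqs)
    data.frame(sequence = seqs,
               sample = sample(c("s1", "s2"), length(seqs), TRUE),
               count = sample(1:50, length(seqs), TRUE),
               stringsAsFactors = FALSE)
}

randomCountTable <- function(nOtu, nSamp, seed, lambda = 60) {
    withr::local_seed(seed)
    m <- matrix(rpois(nOtu * nSamp, lambda) *
                    rbinom(nOtu * nSamp, 1, 0.7), nOtu, nSamp,
                dimnames = list(sprintf("OTU%d", seq_len(nOtu)),
                                sprintf("S%d", seq_len(nSamp))))
    storage.mode(m) <- "integer"
    m
}

randomEuclideanDist <- function(n, dims, seed) {
    withr::local_seed(seed)
    pts <- matrix(rnorm(n * dims), n, dims)
    rownames(pts) <- sprintf("s%d", seq_len(n))
    list(points = pts, dist = as.matrix(dist(pts)))
}
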