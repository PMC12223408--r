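# TSV dialect: optional '#'-prefixed header comments, then a header row
# whose first column is 'otu_id' followed by sample ids; integer cells.

#' Read an OTU table from TSV
#'
#' Strict parser for the package's table dialect: first column `otu_id`,
#' remaining columns one per sample, integer cells. Duplicate ids and
#' negative or non-integer cells are rejected with the offending line
#' number; `#` comment lines are skipped.
#'
#' @param path file path.
#' @return an [OtuTable-class].
#' @export
readOtuTable <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("empty OTU table file: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (header[1] != "otu_id")
        stop(sprintf("%s:%d: first column must be 'otu_id'", path, lineNo[1]))
    samples <- header[-1]
    if (anyDuplicated(samples))
        stop("duplicate sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    body <- lines[-1]
    n <- length(body)
    m <- matrix(0L, n, length(samples),
                dimnames = list(character(n), samples))
    ids <- character(n)
    for (r in seq_len(n)) {
        f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
        if (length(f) != length(header))
            stop(sprintf("%s:%d: expected %d fields, found %d", path,
                         lineNo[r + 1], length(header), length(f)))
        ids[r] <- f[1]
        v <- suppressWarnings(as.numeric(f[-1]))
        if (anyNA(v) || any(v < 0) || any(v != round(v)))
            stop(sprintf("%s:%d: cells must be non-negative integers", path,
                         lineNo[r + 1]))
        m[r, ] <- as.integer(v)
    }
    if (anyDuplicated(ids))
        stop("duplicate otu_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    rownames(m) <- ids
    OtuTable(m)
}

#' Write an OTU table as TSV
#'
#' Canonical ordering — OTUs by descending total (ties by id), samples in
#' their current order — so that repeated writes diff cleanly and
#' write-read round trips are byte-identical.
#'
#' @param table an [OtuTable-class].
#' @param path file path.
#' @param comments character vector written as leading `#` lines (e.g. the
#'   run's seed and parameter fingerprint).
#' @export
writeOtuTable <- function(table, path, comments = character()) {
    stopifnot(is(table, "OtuTable"))
    m <- otuCounts(table)
    tot <- rowSums(m)
    m <- m[order(-tot, rownames(m), method = "radix"), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    writeLines(paste(c("otu_id", colnames(m)), collapse = "\t"), con)
    for (r in seq_len(nrow(m)))
        writeLines(paste(c(rownames(m)[r], m[r, ]), collapse = "\t"), con)
    invisible(path)
}

#' Read a rooted tree with branch lengths from Newick
#'
#' Thin validating wrapper over [ape::read.tree()]: the tree must parse,
#' be rooted, and carry a branch length on every edge (zero lengths are
#' accepted and simply contribute nothing to UniFrac).
#'
#' @param path file path.
#' @return a `phylo`.
#' @export
readNewick <- function(path) {
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
    if (is.null(tr)) stop("Newick parse error in ", path)
    if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
        anyNA(tr$edge.length))
        stop("tree in ", path, " lacks branch lengths on some edges")
    if (!ape::is.rooted(tr)) stop("tree in ", path, " is not rooted")
    if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
    tr
}

#' Write a tree as Newick
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path, digits = 15)
    invisible(path)
}

#' Read sample-labelled reads from annotated FASTA
#'
#' Headers follow the dereplicated dialect `>id;size=N;sample=S` (size
#' defaults to 1, sample to `"sample1"` when missing).
#'
#' @param path FASTA file path(s).
#' @return `data.frame` with columns `id`, `sequence`, `sample`, `count`.
#' @export
readFastaReads <- function(path) {
    out <- lapply(path, function(p) {
        ss <- Biostrings::readDNAStringSet(p)
        hdr <- names(ss)
        id <- sub(";.*$", "", hdr)
        size <- ifelse(grepl(";size=", hdr),
                       as.integer(sub("^.*;size=([0-9]+).*$", "\\1", hdr)), 1L)
        sample <- ifelse(grepl(";sample=", hdr),
                         sub("^.*;sample=([^;]+).*$", "\\1", hdr), "sample1")
        data.frame(id = id, sequence = toupper(as.character(ss)),
                   sample = sample, count = size, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    assertAcgt(unique(out$sequence), "FASTA reads")
    out
}

#' Write sample-labelled reads as annotated FASTA
#'
#' @param reads `data.frame` with `sequence`, `sample`, optional `count`
#'   and `id` columns.
#' @param path file path.
#' @export
writeFastaReads <- function(reads, path) {
    if (is.null(reads$count)) reads$count <- 1L
    if (is.null(reads$id)) reads$id <- sprintf("read%d", seq_len(nrow(reads)))
    hdr <- sprintf("%s;size=%d;sample=%s", reads$id, reads$count,
                   reads$sample)
    ss <- Biostrings::DNAStringSet(reads$sequence)
    names(ss) <- hdr
    Biostrings::writeXStringSet(ss, path, width = 80)
    invisible(path)
}

#' Read a flag file (one id per line)
#'
#' @param path file path; `#` comments and blank lines are ignored.
#' @return character vector of ids.
#' @export
readFlagFile <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !grepl("^#", x)]
}

#' Write a curation report as TSV
#'
#' @param report a [CurationReport-class].
#' @param path file path.
#' @param comments leading `#` comment lines.
#' @export
writeCurationReport <- function(report, path, comments = character()) {
    stopifnot(is(report, "CurationReport"))
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    utils::write.table(report@steps, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a symmetric distance matrix as TSV
#'
#' @param D symmetric matrix with sample dimnames.
#' @param path file path.
#' @param comments leading `#` comment lines.
#' @export
writeDistanceMatrix <- function(D, path, comments = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    writeLines(paste(c("sample_id", colnames(D)), collapse = "\t"), con)
    for (r in seq_len(nrow(D)))
        writeLines(paste(c(rownames(D)[r],
                           format(D[r, ], digits = 12, trim = TRUE)),
                         collapse = "\t"), con)
    invisible(path)
}

#' Write an ordination result as two TSVs
#'
#' `<stem>_coords.tsv` holds sample coordinates, `<stem>_eigen.tsv` the
#' eigenvalues and percent variance per axis.
#'
#' @param ord an [OrdinationResult-class].
#' @param stem path stem.
#' @param comments leading `#` comment lines.
#' @export
writeOrdination <- function(ord, stem, comments = character()) {
    co <- data.frame(sample_id = rownames(ordCoordinates(ord)),
                     ordCoordinates(ord), check.names = FALSE)
    writeTsv(co, paste0(stem, "_coords.tsv"), comments)
    ev <- eigenvalues(ord)
    pv <- percentVariance(ord)
    ei <- data.frame(axis = seq_along(ev), eigenvalue = ev,
                     percent_variance = c(pv, rep(NA, length(ev) -
                                                      length(pv))))
    writeTsv(ei, paste0(stem, "_eigen.tsv"), comments)
    invisible(stem)
}

writeTsv <- function(df, path, comments = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste0("# ", cm), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
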