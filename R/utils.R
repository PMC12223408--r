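# Internal helpers shared across modules.

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

# Deterministic sub-seed from a master seed and a string key. The key (not a
# positional index) drives the hash, so a sample's rarefaction draw depends
# only on its id, never on column order. Kept below 2^31 - 1.
stableSeed <- function(master, key) {
    h <- 0
    for (b in utf8ToInt(as.character(key)))
        h <- (h * 31 + b) %% 2147483563
    as.integer((as.numeric(master) %% 2147483563 * 48271 + h) %% 2147483563)
}

assertCount <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
        stop(sprintf("%s must be a single integer >= %d", name, min),
             call. = FALSE)
    as.integer(x)
}

assertAcgt <- function(seqs, what = "sequence") {
    bad <- grep("[^ACGT]", seqs)
    if (length(bad))
        stop(sprintf("%s contains non-ACGT characters (first offending record: %d, '%s')",
                     what, bad[1], seqs[bad[1]]), call. = FALSE)
    invisible(seqs)
}
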