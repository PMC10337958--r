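# Internal helpers shared across modules.

# Run `expr` under a fixed seed without clobbering the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Canonical unordered pair key: ids sorted lexicographically, joined by "\t".
# Edge sets are compared through these keys everywhere.
pairKey <- function(a, b) {
    swap <- a > b
    ifelse(swap, paste(b, a, sep = "\t"), paste(a, b, sep = "\t"))
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label, so
# independent stages of a workflow use distinct but deterministic streams.
subSeed <- function(seed, label) {
    h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# samples-by-OTUs numeric matrix view used by the statistics layer
sampleMatrix <- function(table) {
    t(SummarizedExperiment::assay(table, "abundance"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
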