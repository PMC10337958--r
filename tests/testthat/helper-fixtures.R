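# Small fixtures built in code; no data files.

# 4 OTUs x 3 samples of counts
toyCounts <- function() {
    m <- matrix(c(2, 3, 5, 0,
                  4, 6, 10, 1,
                  1, 9, 0, 3), nrow = 4,
                dimnames = list(paste0("OTU_", letters[1:4]),
                                c("s1", "s2", "s3")))
    AbundanceTable(m)
}

# 10-sample count table exercising both filter predicates:
#  OTU_tot9  : total 9 (< 10), prevalence 9/10      -> removed by count rule
#  OTU_rare  : nonzero in exactly 1 sample, total 12 -> kept (prevalence 0.10)
#  OTU_both  : abundant and prevalent               -> kept
#  OTU_sparse: nonzero in 0 samples                  -> removed by both
filterFixture <- function() {
    m <- rbind(
        OTU_tot9 = c(rep(1, 9), 0),
        OTU_rare = c(12, rep(0, 9)),
        OTU_both = rep(5, 10),
        OTU_sparse = rep(0, 10))
    colnames(m) <- sprintf("s%02d", 1:10)
    AbundanceTable(m)
}

# relative-abundance cohort with planted pairs, for reconstruction tests
plantedCohort <- function(nSamples = 30, nOtus = 40, nPairs = 10,
                          rho = 0.9, seed = 42, logSd = 1, prefix = "S", ...) {
    pe <- randomPlantedPairs(nOtus, nPairs, seed = seed)
    spec <- syntheticCommunitySpec(nSamples, nOtus, pe, rho = rho,
                                   logSd = logSd, depth = 50000,
                                   seed = seed + 1, ...)
    g <- generateCohort(spec, sampleIds = sprintf("%s%03d", prefix,
                                                  seq_len(nSamples)))
    list(rel = normalizeRelative(g$table), truth = g$truth)
}

# build a network object directly from an edge id matrix (for set-level tests)
madeNetwork <- function(nodes, edges) {
    e <- if (length(edges)) {
        m <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
        data.frame(otu_a = pmin(m[, 1], m[, 2]), otu_b = pmax(m[, 1], m[, 2]),
                   r = 0.5, w = 2, stringsAsFactors = FALSE)
    } else data.frame(otu_a = character(), otu_b = character(),
                      r = numeric(), w = numeric())
    new("CoAbundanceNetwork", nodeIds = nodes, edges = e,
        nEdgesRequested = max(1L, nrow(e)), nCandidates = nrow(e),
        params = list())
}

# independent exhaustive set-arithmetic Jaccard (oracle)
setJaccard <- function(edgesA, edgesB) {
    canon <- function(e) vapply(strsplit(e, "-", fixed = TRUE),
                                function(p) paste(sort(p), collapse = "-"), "")
    a <- unique(canon(edgesA))
    b <- unique(canon(edgesB))
    length(intersect(a, b)) / length(union(a, b))
}
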