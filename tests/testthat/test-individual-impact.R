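# A cohort whose network is pinned by exact functional relations: three OTU
# pairs are perfectly collinear in every sample, so with nEdges = 3 the edge
# set is identical whichever sample is removed.
pinnedCohort <- function(n = 8, jitterSeed = NULL) {
    set.seed(21)
    base <- matrix(runif(3 * n, 0.5, 2), nrow = 3)
    m <- rbind(base,
               base[1, ] * 2,     # partner of OTU 1
               base[2, ] * 1.5,   # partner of OTU 2
               base[3, ] * 3)     # partner of OTU 3
    rownames(m) <- paste0("o", 1:6)
    colnames(m) <- paste0("s", seq_len(n))
    normalizeRelative(AbundanceTable(m))
}

pinnedParams <- networkParams(nEdges = 3, nShuffles = 200, seed = 13)

test_that("removal that leaves the network unchanged has zero impact", {
    rel <- pinnedCohort()
    for (k in c("s1", "s5"))
        expect_equal(directImpact(rel, k, pinnedParams), 0)
})

test_that("direct impact validates its inputs and stays within [0, 1]", {
    rel <- pinnedCohort()
    expect_error(directImpact(rel, "nope", pinnedParams), "not in the cohort")
    expect_error(directImpact(rel[, 1:3], "s1", pinnedParams),
                 "at least 4 samples")
    cohort <- plantedCohort(nSamples = 10, nOtus = 12, nPairs = 3,
                            seed = 31)$rel
    p <- networkParams(nEdges = 8, nShuffles = 150, seed = 3)
    for (k in sampleIds(cohort)[1:4]) {
        di <- directImpact(cohort, k, p)
        expect_gte(di, 0); expect_lte(di, 1)
    }
})

test_that("indirect impact is the shift in similarity to the reference", {
    rel <- pinnedCohort()
    ref <- plantedCohort(nSamples = 10, nOtus = 6, nPairs = 2, seed = 41, prefix = "R")$rel
    # removal changes nothing in the pinned cohort -> indirect impact 0
    expect_equal(indirectImpact(rel, ref, "s2", pinnedParams), 0)
    # and it must equal J(A, B^{n-k}) - J(A, B^n) recomputed explicitly
    cohort <- plantedCohort(nSamples = 10, nOtus = 12, nPairs = 3,
                            seed = 51)$rel
    ref2 <- plantedCohort(nSamples = 10, nOtus = 12, nPairs = 3,
                          seed = 52, prefix = "R")$rel
    p <- networkParams(nEdges = 8, nShuffles = 150, seed = 3)
    k <- sampleIds(cohort)[4]
    a <- reconstructNetwork(ref2, nEdges = 8, nShuffles = 150, seed = 3)
    bn <- reconstructNetwork(cohort, nEdges = 8, nShuffles = 150, seed = 3)
    bnk <- reconstructNetwork(cohort[, setdiff(sampleIds(cohort), k)],
                              nEdges = 8, nShuffles = 150, seed = 3)
    expect_equal(indirectImpact(cohort, ref2, k, p),
                 jaccardSimilarity(a, bnk) - jaccardSimilarity(a, bn))
    # a sample may not sit in its own reference
    expect_error(indirectImpact(cohort, cohort, k, p), "reference")
})

test_that("impact profile reuses one baseline network and is order-stable", {
    cohort <- plantedCohort(nSamples = 10, nOtus = 12, nPairs = 3,
                            seed = 61)$rel
    ref <- plantedCohort(nSamples = 10, nOtus = 12, nPairs = 3,
                         seed = 62, prefix = "R")$rel
    p <- networkParams(nEdges = 8, nShuffles = 150, seed = 3)
    prof <- impactProfile(cohort, ref, p, cohortId = "test")
    sc <- impactScores(prof)
    expect_identical(sc$sample_id, sampleIds(cohort))
    expect_true(all(sc$direct_impact >= 0 & sc$direct_impact <= 1))
    expect_true(all(abs(sc$indirect_impact) <= 1))
    # per-sample functions agree with the profile (same baseline + seed)
    k <- sc$sample_id[3]
    expect_equal(sc$direct_impact[3], directImpact(cohort, k, p))
    expect_equal(sc$indirect_impact[3], indirectImpact(cohort, ref, k, p))
    # permuting the sample order leaves every sample's scores unchanged
    set.seed(71)
    shuffled <- cohort[, sample(ncol(cohort))]
    prof2 <- impactProfile(shuffled, ref, p, cohortId = "test")
    sc2 <- impactScores(prof2)
    expect_equal(sc2$direct_impact[match(sc$sample_id, sc2$sample_id)],
                 sc$direct_impact)
    # pinned cohort: all direct impacts are zero
    profPin <- impactProfile(pinnedCohort(), netParams = pinnedParams)
    expect_true(all(impactScores(profPin)$direct_impact == 0))
})

test_that("signed-rank outlier test matches exact computation", {
    mkProfile <- function(scores, ids = sprintf("g%02d", seq_along(scores))) {
        new("ImpactProfile", cohortId = "c",
            scores = data.frame(sample_id = ids, direct_impact = scores,
                                indirect_impact = NA_real_,
                                p_direct = NA_real_, p_indirect = NA_real_),
            nEdges = 10L, seed = 1L)
    }
    # 26 others around 0.2, k far above: all differences negative, V = 0,
    # exact one-sided p = P(V <= 0) = 1 / 2^26
    set.seed(81)
    others <- round(runif(26, 0.15, 0.25), 7)
    prof <- mkProfile(c(others, 0.9), ids = c(sprintf("g%02d", 1:26), "k"))
    p <- impactOutlierTest(prof, "k")
    expect_equal(p, 1 / 2^26, tolerance = 1e-12)
    expect_lt(p, 0.001)
    # k at the median of the others: no one-sided evidence
    med <- mkProfile(c(sort(others)[13], others),
                     ids = c("k", sprintf("g%02d", 1:26)))
    expect_gte(impactOutlierTest(med, "k"), 0.4)
    # all scores equal: p = 1
    expect_equal(impactOutlierTest(mkProfile(rep(0.3, 10)), "g01"), 1)
    expect_error(impactOutlierTest(mkProfile(rep(0.3, 5)), "g01"),
                 "at least 6")
})

test_that("impact profiles round-trip through TSV", {
    cohort <- plantedCohort(nSamples = 8, nOtus = 10, nPairs = 2,
                            seed = 91)$rel
    prof <- impactProfile(cohort,
                          netParams = networkParams(nEdges = 6,
                                                    nShuffles = 100,
                                                    seed = 2),
                          outlierTests = TRUE)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeImpactProfile(prof, f)
    back <- read.delim(f)
    expect_equal(back$direct_impact, impactScores(prof)$direct_impact)
    expect_true(all(back$p_direct > 0 & back$p_direct <= 1))
})
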