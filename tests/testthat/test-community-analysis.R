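test_that("rJSD matches direct evaluation and its identities", {
    # hand-computed oracle, base 2:
    # m = (0.375, 0.625); KL(x||m) = 0.0465547; KL(y||m) = 0.0510352
    # sqrt(mean) = 0.2208958
    expect_equal(rjsd(c(0.5, 0.5), c(0.25, 0.75)), 0.2208958,
                 tolerance = 1e-6)
    expect_equal(rjsd(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
    # symmetry and bounds on random pairs
    set.seed(4)
    for (i in 1:20) {
        x <- runif(8); y <- runif(8)
        expect_equal(rjsd(x, y), rjsd(y, x))
        expect_gte(rjsd(x, y), 0)
        expect_lte(rjsd(x, y), 1)
    }
    # zero iff renormalized shared-support profiles coincide
    x <- c(0.5, 0.5, 0); y <- c(0.3, 0.3, 0.4)   # shared support equal halves
    expect_equal(rjsd(x, y), 0)
    expect_gt(rjsd(c(0.5, 0.5, 0), c(0.2, 0.4, 0.4)), 0)
    expect_error(rjsd(c(1, 0), c(0, 1)), "shared")
    # scale invariance: renormalization absorbs totals
    expect_equal(rjsd(c(2, 3, 5), c(1, 1, 2)), rjsd(c(0.2, 0.3, 0.5),
                                                    c(0.25, 0.25, 0.5)))
})

test_that("distance matrix equals pairwise scalar rJSD with valid geometry", {
    set.seed(5)
    m <- matrix(runif(24) + 0.01, nrow = 6,
                dimnames = list(paste0("o", 1:6), paste0("s", 1:4)))
    rel <- normalizeRelative(AbundanceTable(m))
    d <- distanceMatrix(rel)
    X <- abundances(rel, samplesAsRows = TRUE)
    for (i in 1:3) for (j in (i + 1):4)
        expect_equal(d[i, j], rjsd(X[i, ], X[j, ]))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    # permutation equivariance in sample order
    relPerm <- rel[, c(3, 1, 4, 2)]
    dPerm <- distanceMatrix(relPerm)
    expect_equal(dPerm, d[c(3, 1, 4, 2), c(3, 1, 4, 2)])
    # duplicated sample has zero distance to its twin
    dup <- AbundanceTable(cbind(abundances(rel), s1b = abundances(rel)[, 1]),
                          isRelative = TRUE)
    expect_equal(distanceMatrix(dup)["s1", "s1b"], 0)
})

test_that("within-group beta diversity enumerates all pairs of the group", {
    set.seed(6)
    m <- matrix(runif(40) + 0.01, nrow = 5,
                dimnames = list(paste0("o", 1:5), paste0("s", 1:8)))
    rel <- normalizeRelative(AbundanceTable(m))
    md <- data.frame(sample_id = paste0("s", 1:8),
                     group = rep(c("healthy", "gdm"), each = 4),
                     timepoint = "W0")
    beta <- withinGroupBeta(rel, md, "healthy", "W0")
    expect_length(beta, choose(4, 2))
    expect_true(all(beta >= 0))
    # two-sample group gives the single pairwise value
    md2 <- md; md2$group[3:4] <- "gdm"
    expect_length(withinGroupBeta(rel, md2, "healthy", "W0"), 1)
    expect_error(withinGroupBeta(rel, md[md$group == "gdm", ],
                                 "healthy", "W0"), "at least 2")
    # identical samples give all-zero beta
    same <- AbundanceTable(matrix(rep(c(0.4, 0.6), 4), nrow = 2,
                                  dimnames = list(c("o1", "o2"),
                                                  paste0("s", 1:4))),
                           isRelative = TRUE)
    mdS <- data.frame(sample_id = paste0("s", 1:4), group = "healthy",
                      timepoint = "W0")
    expect_true(all(withinGroupBeta(same, mdS, "healthy", "W0") == 0))
})

test_that("mean distance to a reference cohort behaves as an average", {
    set.seed(7)
    m <- matrix(runif(30) + 0.01, nrow = 5,
                dimnames = list(paste0("o", 1:5), paste0("s", 1:6)))
    rel <- normalizeRelative(AbundanceTable(m))
    x <- abundances(rel)[, 1]
    expect_equal(meanDistanceToReference(x, rel[, 2]),
                 rjsd(x, abundances(rel)[, 2]))
    allD <- vapply(2:6, function(j) rjsd(x, abundances(rel)[, j]), numeric(1))
    expect_equal(meanDistanceToReference(x, rel[, 2:6]), mean(allD))
    expect_lte(meanDistanceToReference(x, rel[, 2:6]), max(allD))
    # identical reference gives zero
    ident <- AbundanceTable(matrix(rep(x, 3), ncol = 3,
                                   dimnames = list(names(x),
                                                   paste0("r", 1:3))),
                            isRelative = TRUE)
    expect_equal(meanDistanceToReference(x, ident), 0)
})

test_that("PCoA reproduces classical scaling geometry", {
    # three equidistant points: two equal eigenvalues, split 0.5 / 0.5
    d3 <- matrix(1, 3, 3) - diag(3)
    dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
    ord3 <- pcoa(d3, nAxes = 2)
    expect_equal(ord3$explained, c(0.5, 0.5), tolerance = 1e-10)
    # collinear points: first axis carries everything
    x <- c(0, 1, 3, 7)
    dl <- as.matrix(dist(x))
    dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
    ordl <- suppressWarnings(pcoa(dl, nAxes = 2))
    expect_equal(ordl$explained[1], 1, tolerance = 1e-10)
    # Euclidean round trip: coordinates reproduce the input distances
    set.seed(8)
    pts <- matrix(rnorm(21), ncol = 3)
    de <- as.matrix(dist(pts))
    dimnames(de) <- list(paste0("s", 1:7), paste0("s", 1:7))
    orde <- pcoa(de, nAxes = 3)
    rec <- as.matrix(dist(orde$coordinates))
    expect_equal(unname(rec), unname(de), tolerance = 1e-8)
    # asking for more axes than the positive spectrum warns
    expect_warning(pcoa(dl, nAxes = 4), "positive eigenvalue")
})

test_that("rank-sum test matches exact enumeration and rank invariance", {
    a <- 1:10
    b <- 11:20
    # completely separated: exact two-sided p = 2 / choose(20, 10)
    expect_equal(rankSumTest(a, b), 2 / choose(20, 10), tolerance = 1e-12)
    expect_lt(rankSumTest(a, b), 0.001)
    # identical samples: no evidence
    expect_gt(rankSumTest(a, a), 0.9)
    # all values tied
    expect_equal(rankSumTest(rep(1, 5), rep(1, 7)), 1)
    # invariance under monotone transform of the pooled data
    set.seed(9)
    x <- runif(12); y <- runif(15) + 0.2
    expect_equal(rankSumTest(x, y), rankSumTest(exp(x), exp(y)))
    expect_error(rankSumTest(numeric(), y), "non-empty")
})

test_that("differential-abundance screen flags a shifted OTU", {
    set.seed(10)
    base <- matrix(rlnorm(20 * 12), nrow = 20,
                   dimnames = list(sprintf("o%02d", 1:20), paste0("a", 1:12)))
    shifted <- matrix(rlnorm(20 * 12), nrow = 20,
                      dimnames = list(sprintf("o%02d", 1:20), paste0("b", 1:12)))
    shifted["o05", ] <- shifted["o05", ] * 50
    ta <- normalizeRelative(AbundanceTable(base))
    tb <- normalizeRelative(AbundanceTable(shifted))
    res <- differentialAbundance(ta, tb)
    expect_identical(res$otu_id, otuIds(ta))
    expect_lt(res$p_bonferroni[res$otu_id == "o05"], 0.05)
    expect_true(all(res$p_bonferroni >= res$p - 1e-15))
})
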