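test_that("Jaccard similarity matches set arithmetic and its identities", {
    nodes <- letters[1:5]
    expect_equal(jaccardSimilarity(madeNetwork(nodes, c("a-b", "b-c")),
                                   madeNetwork(nodes, c("a-b", "b-c"))), 1)
    expect_equal(jaccardSimilarity(madeNetwork(nodes, c("a-b")),
                                   madeNetwork(nodes, c("c-d"))), 0)
    expect_equal(jaccardSimilarity(madeNetwork(nodes, c("a-b", "b-c", "c-d")),
                                   madeNetwork(nodes, c("b-c", "c-d", "d-e"))),
                 0.5)
    expect_error(jaccardSimilarity(madeNetwork(nodes, character()),
                                   madeNetwork(nodes, character())),
                 "0/0")
})

test_that("Jaccard agrees with exhaustive enumeration on all 4-node networks", {
    nodes <- letters[1:4]
    pairs <- apply(combn(nodes, 2), 2, paste, collapse = "-")
    subsets <- lapply(seq_len(2^6 - 1), function(mask)
        pairs[bitwAnd(mask, 2^(0:5)) > 0])
    for (i in seq(1, length(subsets), by = 7))
        for (j in seq(1, length(subsets), by = 11)) {
            a <- subsets[[i]]; b <- subsets[[j]]
            expect_equal(
                jaccardSimilarity(madeNetwork(nodes, a), madeNetwork(nodes, b)),
                setJaccard(a, b))
        }
    # symmetry and boundedness on random 5-node edge sets
    nodes5 <- letters[1:5]
    pairs5 <- apply(combn(nodes5, 2), 2, paste, collapse = "-")
    set.seed(1)
    for (rep in 1:25) {
        a <- sample(pairs5, sample(1:10, 1))
        b <- sample(pairs5, sample(1:10, 1))
        j1 <- jaccardSimilarity(madeNetwork(nodes5, a), madeNetwork(nodes5, b))
        j2 <- jaccardSimilarity(madeNetwork(nodes5, b), madeNetwork(nodes5, a))
        expect_equal(j1, j2)
        expect_gte(j1, 0); expect_lte(j1, 1)
        expect_equal(j1 == 1, setequal(a, b))
    }
})

test_that("edge-shuffled ensemble matches the hypergeometric expectation", {
    set.seed(2)
    nodes <- sprintf("n%02d", 1:20)
    pairs <- apply(combn(nodes, 2), 2, paste, collapse = "-")
    netA <- madeNetwork(nodes, sample(pairs, 40))
    netB <- madeNetwork(nodes, sample(pairs, 25))
    nulls <- shuffledNetworkEnsemble(netA, netB, nRealizations = 2000, seed = 8)
    # closed-form oracle: intersection is hypergeometric(m, M - m, n)
    M <- choose(20, 2)
    k <- 0:25
    ej <- sum(dhyper(k, 40, M - 40, 25) * k / (40 + 25 - k))
    expect_lt(abs(mean(nulls) - ej), 3 * sd(nulls) / sqrt(length(nulls)))
    # forced overlap: complete networks always coincide
    n3 <- letters[1:3]
    full <- madeNetwork(n3, c("a-b", "a-c", "b-c"))
    expect_true(all(shuffledNetworkEnsemble(full, full, 50, seed = 1) == 1))
    # too many edges for the node universe
    over <- madeNetwork(n3, c("a-b", "a-c", "b-c"))
    over@nodeIds <- c("a", "b")
    expect_error(shuffledNetworkEnsemble(over, over, 10), "exceeds")
})

test_that("empirical p is inclusive, monotone and seed-stable", {
    set.seed(3)
    nodes <- sprintf("n%02d", 1:15)
    pairs <- apply(combn(nodes, 2), 2, paste, collapse = "-")
    a <- sample(pairs, 30)
    netA <- madeNetwork(nodes, a)
    # observed J = 1 vs itself: no null realization reaches 1
    cmpSelf <- compareWithNull(netA, netA, nRealizations = 400, seed = 5)
    expect_equal(jaccard(cmpSelf), 1)
    expect_equal(pEmpirical(cmpSelf), 0)
    # observed J = 0: every null value >= 0
    netC <- madeNetwork(nodes, setdiff(pairs, a)[1:30])
    cmp0 <- compareWithNull(netA, netC, nRealizations = 400, seed = 5)
    expect_equal(jaccard(cmp0), 0)
    expect_equal(pEmpirical(cmp0), 1)
    # monotone: p computed against one ensemble is non-increasing in J
    nulls <- nullJaccards(cmp0)
    ps <- vapply(seq(0, 1, 0.1), function(j) mean(nulls >= j), numeric(1))
    expect_true(all(diff(ps) <= 0))
    # determinism
    cmpAgain <- compareWithNull(netA, netC, nRealizations = 400, seed = 5)
    expect_identical(pEmpirical(cmpAgain), pEmpirical(cmp0))
    expect_identical(nullJaccards(cmpAgain), nullJaccards(cmp0))
})

test_that("indirect group shift reports similarity to the reference", {
    nodes <- letters[1:6]
    ref <- madeNetwork(nodes, c("a-b", "b-c", "c-d", "d-e"))
    before <- madeNetwork(nodes, c("a-b", "b-c"))
    shift <- indirectGroupShift(ref, before, ref)
    expect_equal(unname(shift["after"]), 1)
    expect_equal(unname(indirectGroupShift(ref, before, before)["before"]),
                 unname(indirectGroupShift(ref, before, before)["after"]))
    # rewiring half of a subset network lowers similarity to the reference
    set.seed(9)
    after <- madeNetwork(nodes, c("a-b", "e-f"))  # one edge kept, one rewired
    expect_lt(unname(indirectGroupShift(ref, before, after)["after"]),
              unname(indirectGroupShift(ref, before, after)["before"]))
})

test_that("subject bootstrap yields a similarity distribution in [0, 1]", {
    cohortA <- plantedCohort(nSamples = 16, nOtus = 12, nPairs = 3,
                             seed = 5)$rel
    cohortB <- plantedCohort(nSamples = 16, nOtus = 12, nPairs = 3,
                             seed = 6)$rel
    js <- jaccardBootstrap(cohortA, cohortB,
                           networkParams(nEdges = 10, nShuffles = 100,
                                         seed = 2),
                           nBoot = 6, seed = 3)
    expect_length(js, 6)
    expect_true(all(js >= 0 & js <= 1))
    js2 <- jaccardBootstrap(cohortA, cohortB,
                            networkParams(nEdges = 10, nShuffles = 100,
                                          seed = 2),
                            nBoot = 6, seed = 3)
    expect_identical(js, js2)
})
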