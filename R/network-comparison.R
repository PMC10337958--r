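#' Jaccard similarity between two networks' edge sets
#'
#' `|E_A ∩ E_B| / |E_A ∪ E_B|`, with edges compared as unordered OTU-id
#' pairs.  This single overlap measure quantifies how much of the
#' co-abundance structure two cohorts share.
#'
#' @param netA,netB [CoAbundanceNetwork-class] objects on a shared node
#'   universe; at least one must have edges.
#' @return Jaccard similarity in \[0, 1\].
#' @examples
#' ## identical edge sets give 1, disjoint sets give 0
#' @export
jaccardSimilarity <- function(netA, netB) {
    ka <- edgeKeys(netA)
    kb <- edgeKeys(netB)
    u <- length(union(ka, kb))
    if (u == 0)
        stop("both edge sets are empty; Jaccard undefined (0/0)",
             call. = FALSE)
    length(intersect(ka, kb)) / u
}

#' Jaccard distribution of edge-shuffled null networks
#'
#' Each realization replaces both networks' edge sets by uniform random edge
#' sets of the same sizes over the same node universe (all `C(n, 2)` pairs
#' equally likely, no degree preservation), and records the Jaccard
#' similarity of the two shuffled networks.  This is the null ensemble
#' against which an observed between-cohort similarity is judged: two
#' independent networks of the given sizes share edges only by chance.
#'
#' @param netA,netB [CoAbundanceNetwork-class] objects on a shared node
#'   universe.
#' @param nRealizations number of shuffled realizations (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `nRealizations` null Jaccard values.
#' @export
shuffledNetworkEnsemble <- function(netA, netB, nRealizations = 1000,
                                    seed = 1) {
    if (nRealizations < 1)
        stop("need at least one realization", call. = FALSE)
    nodes <- nodeIds(netA)
    if (!setequal(nodes, nodeIds(netB)))
        stop("networks must share one node universe", call. = FALSE)
    M <- length(nodes) * (length(nodes) - 1) / 2
    ma <- nEdges(netA)
    mb <- nEdges(netB)
    if (ma > M || mb > M)
        stop("edge count exceeds the number of node pairs", call. = FALSE)
    withSeed(seed, vapply(seq_len(nRealizations), function(b) {
        ea <- sample.int(M, ma)
        eb <- sample.int(M, mb)
        i <- length(intersect(ea, eb))
        i / (ma + mb - i)
    }, numeric(1)))
}

#' Compare two networks against an edge-shuffled null ensemble
#'
#' Bundles the observed Jaccard similarity, the null ensemble from
#' [shuffledNetworkEnsemble()], and the one-sided empirical p-value: the
#' fraction of shuffled realizations whose Jaccard is greater than or equal
#' to the observed value.  A returned p of 0 means no realization reached
#' the observed value, i.e. p < 1 / `nRealizations`.
#'
#' @inheritParams shuffledNetworkEnsemble
#' @return a [NetworkComparison-class].
#' @export
compareWithNull <- function(netA, netB, nRealizations = 1000, seed = 1) {
    j <- jaccardSimilarity(netA, netB)
    ka <- edgeKeys(netA)
    kb <- edgeKeys(netB)
    nulls <- shuffledNetworkEnsemble(netA, netB,
                                     nRealizations = nRealizations,
                                     seed = seed)
    new("NetworkComparison", jaccard = j,
        nIntersection = length(intersect(ka, kb)),
        nUnion = length(union(ka, kb)),
        nullJaccards = nulls,
        pEmpirical = mean(nulls >= j - 1e-15))
}

#' @rdname NetworkComparison-accessors
#' @export
setMethod("jaccard", "NetworkComparison", function(x) x@jaccard)

#' Accessors for NetworkComparison
#'
#' @param x a [NetworkComparison-class].
#' @name NetworkComparison-accessors
#' @aliases jaccard nullJaccards pEmpirical
NULL

#' @rdname NetworkComparison-accessors
#' @export
setMethod("nullJaccards", "NetworkComparison", function(x) x@nullJaccards)

#' @rdname NetworkComparison-accessors
#' @export
setMethod("pEmpirical", "NetworkComparison", function(x) x@pEmpirical)

setMethod("show", "NetworkComparison", function(object) {
    cat(sprintf("NetworkComparison: J = %.4f (%d / %d edges shared)\n",
                object@jaccard, object@nIntersection, object@nUnion))
    if (length(object@nullJaccards)) {
        cat(sprintf("  null: mean %.4f, sd %.4f over %d realizations\n",
                    mean(object@nullJaccards), stats::sd(object@nullJaccards),
                    length(object@nullJaccards)))
        p <- object@pEmpirical
        cat(sprintf("  empirical p %s\n",
                    if (p == 0)
                        sprintf("< %.3g", 1 / length(object@nullJaccards))
                    else sprintf("= %.3g", p)))
    }
})

#' Similarity of a target cohort to a reference, before and after
#'
#' Evaluates a change in a target cohort (e.g. a diet intervention) without
#' comparing the target groups to each other directly: both the before and
#' the after network are compared to the same reference network, and a drop
#' in similarity is read as divergence from the reference.
#'
#' @param reference reference [CoAbundanceNetwork-class] (e.g. healthy, first
#'   timepoint).
#' @param targetBefore,targetAfter target cohort networks at the two
#'   timepoints.
#' @return named numeric vector `c(before = , after = )` of Jaccard
#'   similarities to the reference.
#' @export
indirectGroupShift <- function(reference, targetBefore, targetAfter) {
    c(before = jaccardSimilarity(reference, targetBefore),
        after = jaccardSimilarity(reference, targetAfter))
}

#' Reconstruction parameters as a list
#'
#' Convenience bundle of the parameters shared by every network
#' reconstruction in a comparison or impact analysis.
#'
#' @param nEdges fixed edge budget (default 500).
#' @param wThreshold Z-score significance threshold (default 1).
#' @param nShuffles shuffle realizations for the correlation null
#'   (default 1000).
#' @param seed master seed (default 1).
#' @param rankAbs rank candidate edges by `|r|` instead of signed `r`.
#' @return a named list accepted by the `netParams` arguments.
#' @export
networkParams <- function(nEdges = 500, wThreshold = 1.0, nShuffles = 1000,
                          seed = 1, rankAbs = FALSE) {
    stopifnot(nEdges > 0, nShuffles >= 2)
    list(nEdges = nEdges, wThreshold = wThreshold, nShuffles = nShuffles,
         seed = seed, rankAbs = rankAbs)
}

reconstructWithParams <- function(table, netParams) {
    reconstructNetwork(table,
                       nEdges = netParams$nEdges %||% 500,
                       wThreshold = netParams$wThreshold %||% 1.0,
                       nShuffles = netParams$nShuffles %||% 1000,
                       seed = netParams$seed %||% 1,
                       rankAbs = isTRUE(netParams$rankAbs))
}

#' Bootstrap distribution of the Jaccard similarity of two cohorts
#'
#' A single pair of cohorts yields a single Jaccard value; to attach a
#' distribution to it (e.g. for rank-based comparisons of similarities), each
#' cohort's subjects are resampled with replacement, both networks are
#' rebuilt under the same parameters, and the Jaccard of the rebuilt
#' networks is recorded.  This subject-level bootstrap is this package's
#' construction for turning one network pair into a similarity distribution.
#'
#' @param tableA,tableB relative-abundance [AbundanceTable-class] cohorts on
#'   a shared OTU set.
#' @param netParams list from [networkParams()].
#' @param nBoot bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @return numeric vector of `nBoot` Jaccard values.
#' @export
jaccardBootstrap <- function(tableA, tableB, netParams = networkParams(),
                             nBoot = 100, seed = 1) {
    idxA <- withSeed(subSeed(seed, "bootA"), replicate(
        nBoot, sample.int(ncol(tableA), replace = TRUE), simplify = FALSE))
    idxB <- withSeed(subSeed(seed, "bootB"), replicate(
        nBoot, sample.int(ncol(tableB), replace = TRUE), simplify = FALSE))
    vapply(seq_len(nBoot), function(b) {
        ta <- resampleSamples(tableA, idxA[[b]])
        tb <- resampleSamples(tableB, idxB[[b]])
        jaccardSimilarity(reconstructWithParams(ta, netParams),
                          reconstructWithParams(tb, netParams))
    }, numeric(1))
}

# Subset samples by (possibly repeated) indices; repeated samples get
# suffixed ids so identifiers stay unique.
resampleSamples <- function(table, idx) {
    a <- abundances(table)[, idx, drop = FALSE]
    colnames(a) <- make.unique(colnames(a))
    AbundanceTable(a, isRelative = isRelative(table))
}
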