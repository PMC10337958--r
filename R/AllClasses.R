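#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' AbundanceTable: an OTU abundance matrix with sample annotations
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay `"abundance"` with OTUs as rows and samples as columns
#' (the Bioconductor convention; statistical operations that treat samples as
#' observations transpose internally).  A logical flag records whether the
#' table holds raw counts or relative abundances; for relative tables every
#' sample (column) must sum to one within `1e-9`.
#'
#' @slot .  Inherits all slots from `SummarizedExperiment`.
#' @seealso [AbundanceTable()], [filterOtus()], [normalizeRelative()]
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is missing")
    else {
        a <- assay(object, "abundance")
        if (is.null(rownames(a)) || is.null(colnames(a)))
            msg <- c(msg, "abundance matrix must have OTU and sample names")
        else {
            if (anyDuplicated(rownames(a)))
                msg <- c(msg, "duplicated OTU identifiers")
            if (anyDuplicated(colnames(a)))
                msg <- c(msg, "duplicated sample identifiers")
        }
        if (any(!is.finite(a)))
            msg <- c(msg, "non-finite abundance values")
        else if (any(a < 0))
            msg <- c(msg, "negative abundance values")
        else if (isTRUE(metadata(object)$is_relative) && ncol(a) > 0) {
            cs <- colSums(a)
            if (any(abs(cs - 1) > 1e-9))
                msg <- c(msg, "relative table has sample sums differing from 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' CoAbundanceNetwork: a binary OTU co-abundance network
#'
#' Nodes are OTU identifiers; edges are unordered OTU pairs whose Pearson
#' correlation passed the shuffle Z-score significance filter and survived the
#' fixed-edge-budget ranking.  Each edge carries its Pearson coefficient `r`
#' and its Z-score `w` relative to the permutation null.
#'
#' @slot nodeIds character, the ordered OTU universe of the network.
#' @slot edges data.frame with columns `otu_a`, `otu_b` (with
#'   `otu_a < otu_b` lexicographically), `r`, `w`; rows ordered by the ranking
#'   used at construction (decreasing ranking score).
#' @slot nEdgesRequested integer, the fixed edge budget asked for.
#' @slot nCandidates integer, number of pairs that passed the W filter (so a
#'   shortfall occurred when `nCandidates < nEdgesRequested`).
#' @slot params list, reconstruction parameters (w_threshold, n_shuffles,
#'   rank_abs, seed) recorded for provenance.
#' @export
setClass("CoAbundanceNetwork",
    representation(nodeIds = "character", edges = "data.frame",
                   nEdgesRequested = "integer", nCandidates = "integer",
                   params = "list"))

setValidity("CoAbundanceNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("otu_a", "otu_b", "r", "w")
    if (!all(need %in% names(e)))
        return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(object@nodeIds))
        msg <- c(msg, "duplicated node identifiers")
    if (nrow(e)) {
        if (!all(c(e$otu_a, e$otu_b) %in% object@nodeIds))
            msg <- c(msg, "edge endpoint outside the node set")
        if (any(e$otu_a == e$otu_b))
            msg <- c(msg, "self-loop edge")
        if (any(e$otu_a > e$otu_b))
            msg <- c(msg, "edges must be stored with otu_a < otu_b")
        if (anyDuplicated(paste(e$otu_a, e$otu_b)))
            msg <- c(msg, "duplicated edges")
    }
    if (nrow(e) > object@nEdgesRequested)
        msg <- c(msg, "more edges than requested")
    n <- length(object@nodeIds)
    if (nrow(e) > n * (n - 1) / 2)
        msg <- c(msg, "more edges than node pairs")
    if (length(msg)) msg else TRUE
})

#' NetworkComparison: Jaccard similarity with an edge-shuffled null
#'
#' Result of comparing two co-abundance networks: the observed Jaccard index
#' of their edge sets, the Jaccard values of an ensemble of edge-shuffled
#' null networks, and the one-sided empirical p-value (fraction of null
#' realizations with Jaccard greater than or equal to the observed value).
#'
#' @slot jaccard observed Jaccard similarity in \[0, 1\].
#' @slot nIntersection,nUnion integer edge-set intersection and union sizes.
#' @slot nullJaccards numeric, Jaccard value of each null realization.
#' @slot pEmpirical empirical p-value; `0` means no null realization reached
#'   the observed value, i.e. p < 1 / length(nullJaccards).
#' @export
setClass("NetworkComparison",
    representation(jaccard = "numeric", nIntersection = "integer",
                   nUnion = "integer", nullJaccards = "numeric",
                   pEmpirical = "numeric"))

setValidity("NetworkComparison", function(object) {
    msg <- character()
    if (object@nUnion > 0 &&
        abs(object@jaccard - object@nIntersection / object@nUnion) > 1e-12)
        msg <- c(msg, "jaccard != nIntersection / nUnion")
    if (length(object@nullJaccards)) {
        p <- mean(object@nullJaccards >= object@jaccard - 1e-15)
        if (abs(p - object@pEmpirical) > 1e-12)
            msg <- c(msg, "pEmpirical inconsistent with null ensemble")
    }
    if (length(msg)) msg else TRUE
})

#' ImpactProfile: leave-one-out network impact of every sample in a cohort
#'
#' For each sample k the profile stores the direct impact
#' `1 - J(B^n, B^(n-k))` (Jaccard dissimilarity between the cohort network
#' with and without k) and, when a reference cohort was supplied, the
#' indirect impact `J(A, B^(n-k)) - J(A, B^n)` (shift of the cohort network
#' towards the reference network A when k is removed).
#'
#' @slot cohortId character label of the cohort.
#' @slot scores data.frame with columns `sample_id`, `direct_impact`,
#'   `indirect_impact` (NA when no reference), `p_direct`, `p_indirect`
#'   (signed-rank outlier p-values, NA unless computed).
#' @slot nEdges integer edge budget used for all reconstructions.
#' @slot seed integer master seed shared by all reconstructions so that the
#'   full-cohort network is identical across leave-one-out evaluations.
#' @export
setClass("ImpactProfile",
    representation(cohortId = "character", scores = "data.frame",
                   nEdges = "integer", seed = "integer"))

setValidity("ImpactProfile", function(object) {
    s <- object@scores
    need <- c("sample_id", "direct_impact", "indirect_impact")
    if (!all(need %in% names(s)))
        return(sprintf("scores must have columns %s", paste(need, collapse = ", ")))
    msg <- character()
    d <- s$direct_impact
    if (any(!is.na(d) & (d < -1e-12 | d > 1 + 1e-12)))
        msg <- c(msg, "direct impact outside [0, 1]")
    i <- s$indirect_impact
    if (any(!is.na(i) & (i < -1 - 1e-12 | i > 1 + 1e-12)))
        msg <- c(msg, "indirect impact outside [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' SyntheticCommunitySpec: parameters of the planted-network generator
#'
#' Describes a synthetic cohort: a latent Gaussian copula with unit-diagonal
#' correlation matrix carrying `rho` on each planted OTU pair, mapped through
#' per-OTU log-normal marginals, closed to relative abundances and sampled to
#' integer counts by a multinomial draw at fixed sequencing depth.  Selected
#' samples can be turned into correlation-disrupted outliers.
#'
#' @slot nSamples,nOtus integer dimensions of the cohort.
#' @slot plantedEdges two-column integer matrix of OTU index pairs receiving
#'   latent correlation `rho` (may have zero rows).
#' @slot rho target latent pairwise correlation, strictly in (0, 1).
#' @slot logMean,logSd per-OTU location and scale of the log-normal marginals
#'   (recycled to `nOtus`).
#' @slot depth integer sequencing depth (reads per sample).
#' @slot outliers list of `list(sample = index, mode = "permute"|"foreign")`.
#' @slot seed integer seed making generation deterministic.
#' @export
setClass("SyntheticCommunitySpec",
    representation(nSamples = "integer", nOtus = "integer",
                   plantedEdges = "matrix", rho = "numeric",
                   logMean = "numeric", logSd = "numeric",
                   depth = "integer", outliers = "list", seed = "integer"))

setValidity("SyntheticCommunitySpec", function(object) {
    msg <- character()
    if (object@nSamples < 2L) msg <- c(msg, "need at least 2 samples")
    if (object@nOtus < 2L) msg <- c(msg, "need at least 2 OTUs")
    pe <- object@plantedEdges
    if (nrow(pe)) {
        if (ncol(pe) != 2L) msg <- c(msg, "plantedEdges must have 2 columns")
        else {
            if (any(pe[, 1] == pe[, 2])) msg <- c(msg, "planted self-pair")
            if (any(pe < 1 | pe > object@nOtus))
                msg <- c(msg, "planted edge index out of range")
        }
        if (object@rho <= 0 || object@rho >= 1)
            msg <- c(msg, "rho must lie strictly in (0, 1)")
    }
    if (object@depth < 1L) msg <- c(msg, "depth must be positive")
    if (length(object@logMean) != object@nOtus ||
        length(object@logSd) != object@nOtus)
        msg <- c(msg, "logMean / logSd must have length nOtus")
    if (length(msg)) msg else TRUE
})
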