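#' Pairwise Pearson correlations between OTUs
#'
#' Computes the Pearson correlation between every unordered pair of OTUs
#' across the samples of one cohort.  Pairs involving an OTU that is constant
#' across samples have no defined correlation and are returned as `NA`; they
#' are excluded from network reconstruction.
#'
#' @param table an [AbundanceTable-class] of relative abundances with at
#'   least 3 samples.
#' @return symmetric numeric matrix of correlations, dimnames the OTU ids,
#'   `NA` where undefined.
#' @export
pairwisePearson <- function(table) {
    X <- sampleMatrix(table)
    if (nrow(X) < 3)
        stop("need at least 3 samples to correlate OTUs", call. = FALSE)
    sds <- apply(X, 2, stats::sd)
    C <- suppressWarnings(stats::cor(X))
    C[sds == 0, ] <- NA_real_
    C[, sds == 0] <- NA_real_
    diag(C) <- 1
    C
}

# Monte-Carlo moments of the permutation null of Pearson correlation.
# Each realization permutes every OTU's abundance vector independently
# (resampling from its empirical distribution without replacement), then the
# full correlation matrix of the shuffled table is taken; mean and standard
# deviation are accumulated per pair over nShuffles realizations.  Sharing
# one shuffled table across pairs leaves each pair's null draws exact and is
# what makes the procedure tractable at thousands of pairs.
nullCorrelationMoments <- function(X, nShuffles) {
    n <- nrow(X)
    p <- ncol(X)
    if (nShuffles < 2) stop("need at least 2 shuffles", call. = FALSE)
    Z <- scale(X)             # permutation leaves column mean/sd unchanged
    colIdx <- rep(seq_len(p), each = n)
    s1 <- matrix(0, p, p)
    s2 <- matrix(0, p, p)
    for (b in seq_len(nShuffles)) {
        ord <- order(colIdx, stats::runif(n * p))
        Zs <- matrix(Z[ord], n, p)
        C <- crossprod(Zs) / (n - 1)
        s1 <- s1 + C
        s2 <- s2 + C * C
    }
    m <- s1 / nShuffles
    v <- pmax(s2 / nShuffles - m * m, 0) * nShuffles / (nShuffles - 1)
    dimnames(m) <- dimnames(v) <- list(colnames(X), colnames(X))
    list(mean = m, sd = sqrt(v))
}

#' Shuffle null distribution of the correlation of one OTU pair
#'
#' Estimates the mean and standard deviation of the Pearson correlation of a
#' single OTU pair under the null in which each OTU's abundance vector is
#' independently permuted across samples (a resample from its own empirical
#' abundance distribution, without replacement), destroying any association
#' while preserving both marginals exactly.  With `replace = TRUE` the values
#' are instead drawn with replacement from the empirical distribution.
#'
#' @param table an [AbundanceTable-class] with at least 3 samples.
#' @param pair character vector of two OTU ids.
#' @param nShuffles number of shuffle realizations (default 1000).
#' @param seed integer seed making the estimate reproducible.
#' @param replace logical; resample with replacement instead of permuting.
#' @return list with elements `mean` and `sd` of the null correlations.
#' @export
shuffleNullForPair <- function(table, pair, nShuffles = 1000, seed = 1,
                               replace = FALSE) {
    stopifnot(length(pair) == 2)
    X <- sampleMatrix(table)
    if (!all(pair %in% colnames(X)))
        stop("unknown OTU id(s): ",
             paste(setdiff(pair, colnames(X)), collapse = ", "), call. = FALSE)
    x <- X[, pair[1]]
    y <- X[, pair[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("pair has an OTU with zero variance; correlation undefined",
             call. = FALSE)
    n <- length(x)
    rs <- withSeed(seed, vapply(seq_len(nShuffles), function(b) {
        xs <- sample(x, n, replace = replace)
        ys <- sample(y, n, replace = replace)
        suppressWarnings(stats::cor(xs, ys))
    }, numeric(1)))
    rs <- rs[is.finite(rs)]
    if (length(rs) < 2)
        stop("degenerate shuffles: null distribution undefined", call. = FALSE)
    list(mean = mean(rs), sd = stats::sd(rs))
}

#' Z-score of a correlation against its shuffle null
#'
#' Standardizes an observed Pearson coefficient by the mean and standard
#' deviation of its shuffle null: `W = (r - nullMean) / nullSd`.  Larger W
#' means a more significant correlation; W below 1 is conventionally treated
#' as non-significant and filtered out of the network.
#'
#' @param r observed Pearson coefficient.
#' @param nullMean,nullSd moments of the shuffle null; `nullSd` must be
#'   positive.
#' @return the Z-score W.
#' @export
zscoreW <- function(r, nullMean, nullSd) {
    if (any(nullSd <= 0))
        stop("null standard deviation must be positive; W undefined",
             call. = FALSE)
    (r - nullMean) / nullSd
}

#' All candidate edges with correlation and shuffle Z-score
#'
#' Computes, for every unordered OTU pair with a defined correlation, the
#' Pearson coefficient, the Monte-Carlo null moments and the Z-score W.
#' Both [reconstructNetwork()] and [networkSizeSweep()] are built on this.
#'
#' Samples and OTUs are put into a canonical (lexicographic) order before
#' the Monte-Carlo draws, so the result is invariant to the order in which
#' samples or OTU columns are supplied.
#'
#' @param table an [AbundanceTable-class] of relative abundances, >= 3 samples.
#' @param nShuffles shuffle realizations per pair (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `otu_a`, `otu_b` (`otu_a < otu_b`), `r`,
#'   `null_mean`, `null_sd`, `w`, one row per defined pair.
#' @export
edgeCandidates <- function(table, nShuffles = 1000, seed = 1) {
    X <- sampleMatrix(table)
    if (nrow(X) < 3)
        stop("need at least 3 samples to reconstruct a network", call. = FALSE)
    X <- X[order(rownames(X)), order(colnames(X)), drop = FALSE]
    ok <- apply(X, 2, stats::sd) > 0
    Xv <- X[, ok, drop = FALSE]
    if (ncol(Xv) < 2)
        stop("fewer than 2 OTUs with non-zero variance", call. = FALSE)
    C <- stats::cor(Xv)
    mom <- withSeed(seed, nullCorrelationMoments(Xv, nShuffles))
    ut <- upper.tri(C)
    ij <- which(ut, arr.ind = TRUE)
    ids <- colnames(Xv)
    sd0 <- mom$sd[ut]
    data.frame(otu_a = ids[ij[, 1]], otu_b = ids[ij[, 2]],
               r = C[ut], null_mean = mom$mean[ut], null_sd = sd0,
               w = ifelse(sd0 > 0, (C[ut] - mom$mean[ut]) / sd0, NA_real_),
               stringsAsFactors = FALSE)
}

#' Reconstruct a fixed-size co-abundance network for one cohort
#'
#' The network is built in three steps: (1) the Pearson correlation of every
#' OTU pair is computed; (2) pairs whose shuffle Z-score W falls below
#' `wThreshold` are filtered out as non-significant; (3) the surviving pairs
#' are ranked by Pearson coefficient (signed, by default) in decreasing
#' order and the top `nEdges` become the edges of a binary network.  Fixing
#' the edge count removes the size bias that would otherwise confound
#' structural comparisons between cohorts.  If fewer than `nEdges` pairs
#' survive the filter, all of them are kept and the shortfall is recorded
#' (see [edgeShortfall()]).  Ties at the cutoff are broken by lexicographic
#' order of the OTU-id pair.
#'
#' @param table an [AbundanceTable-class] of relative abundances, >= 3 samples.
#' @param nEdges fixed edge budget (default 500).
#' @param wThreshold minimum Z-score W for a pair to be considered
#'   significant (default 1).
#' @param nShuffles shuffle realizations for the null (default 1000).
#' @param seed integer seed; identical seeds give identical networks.
#' @param rankAbs logical; rank by `|r|` instead of signed `r` (default
#'   `FALSE`: strong negative correlations never enter the network).
#' @return a [CoAbundanceNetwork-class] whose node set is the table's full
#'   OTU list.
#' @export
reconstructNetwork <- function(table, nEdges = 500, wThreshold = 1.0,
                               nShuffles = 1000, seed = 1, rankAbs = FALSE) {
    if (nEdges <= 0)
        stop("nEdges must be positive", call. = FALSE)
    cand <- edgeCandidates(table, nShuffles = nShuffles, seed = seed)
    cand <- cand[!is.na(cand$w) & cand$w >= wThreshold, , drop = FALSE]
    score <- if (rankAbs) abs(cand$r) else cand$r
    ord <- order(-score, cand$otu_a, cand$otu_b)
    sel <- cand[ord, , drop = FALSE][seq_len(min(nEdges, nrow(cand))), ,
                                     drop = FALSE]
    rownames(sel) <- NULL
    new("CoAbundanceNetwork",
        nodeIds = otuIds(table),
        edges = sel[, c("otu_a", "otu_b", "r", "w")],
        nEdgesRequested = as.integer(nEdges),
        nCandidates = as.integer(nrow(cand)),
        params = list(w_threshold = wThreshold, n_shuffles = nShuffles,
                      seed = seed, rank_abs = rankAbs))
}

#' Network size as a function of the W threshold
#'
#' For each threshold, counts the OTU pairs whose shuffle Z-score W reaches
#' it — the size an unconstrained (no fixed edge budget) network would have.
#' The count is non-increasing in the threshold, and differs between cohorts
#' at any fixed threshold, which is why comparisons use a fixed edge count.
#'
#' @param table an [AbundanceTable-class] of relative abundances.
#' @param wThresholds numeric vector of thresholds.
#' @inheritParams edgeCandidates
#' @return named numeric vector mapping each threshold to its edge count.
#' @export
networkSizeSweep <- function(table, wThresholds, nShuffles = 1000, seed = 1) {
    if (!length(wThresholds))
        stop("wThresholds must be non-empty", call. = FALSE)
    cand <- edgeCandidates(table, nShuffles = nShuffles, seed = seed)
    w <- cand$w[!is.na(cand$w)]
    counts <- vapply(wThresholds, function(t) sum(w >= t), numeric(1))
    names(counts) <- as.character(wThresholds)
    counts
}

#' @rdname CoAbundanceNetwork-accessors
#' @export
setMethod("nodeIds", "CoAbundanceNetwork", function(x) x@nodeIds)

#' Accessors for CoAbundanceNetwork
#'
#' `networkEdges` returns the edge table (columns `otu_a`, `otu_b`, `r`, `w`),
#' `edgeKeys` the canonical unordered-pair keys used for set comparisons,
#' `nEdges` the realized edge count, `nodeIds` the node universe and
#' `edgeShortfall` how many edges short of the requested budget the W filter
#' left the network.
#'
#' @param x a [CoAbundanceNetwork-class].
#' @name CoAbundanceNetwork-accessors
#' @aliases nodeIds networkEdges edgeKeys nEdges edgeShortfall
NULL

#' @rdname CoAbundanceNetwork-accessors
#' @export
setMethod("networkEdges", "CoAbundanceNetwork", function(x) x@edges)

#' @rdname CoAbundanceNetwork-accessors
#' @export
setMethod("edgeKeys", "CoAbundanceNetwork",
    function(x) pairKey(x@edges$otu_a, x@edges$otu_b))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setMethod("nEdges", "CoAbundanceNetwork", function(x) nrow(x@edges))

#' @rdname CoAbundanceNetwork-accessors
#' @export
setMethod("edgeShortfall", "CoAbundanceNetwork",
    function(x) max(0L, x@nEdgesRequested - nrow(x@edges)))

setMethod("show", "CoAbundanceNetwork", function(object) {
    cat(sprintf("CoAbundanceNetwork: %d nodes, %d edges (requested %d)\n",
                length(object@nodeIds), nrow(object@edges),
                object@nEdgesRequested))
    if (edgeShortfall(object) > 0)
        cat(sprintf("  shortfall: only %d pairs passed the W filter\n",
                    object@nCandidates))
    if (nrow(object@edges))
        cat(sprintf("  Pearson r range: [%.3f, %.3f]\n",
                    min(object@edges$r), max(object@edges$r)))
})

#' Write a network's edge list to a tab-separated file
#'
#' Columns `otu_a`, `otu_b`, `pearson_r`, `z_score`, with
#' `otu_a < otu_b` lexicographically.
#'
#' @param net a [CoAbundanceNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
    e <- networkEdges(net)
    out <- data.frame(otu_a = e$otu_a, otu_b = e$otu_b,
                      pearson_r = e$r, z_score = e$w)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a network edge list written by [writeEdgeList()]
#'
#' @param path path to the edge-list TSV.
#' @param nodeIds optional node universe; defaults to the OTUs present in
#'   the edge list.
#' @return a [CoAbundanceNetwork-class].
#' @export
readEdgeList <- function(path, nodeIds = NULL) {
    e <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("otu_a", "otu_b", "pearson_r", "z_score")
    if (!all(need %in% names(e)))
        stop("edge list must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    swap <- e$otu_a > e$otu_b
    tmp <- e$otu_a[swap]; e$otu_a[swap] <- e$otu_b[swap]; e$otu_b[swap] <- tmp
    nodes <- nodeIds %||% sort(unique(c(e$otu_a, e$otu_b)))
    new("CoAbundanceNetwork", nodeIds = nodes,
        edges = data.frame(otu_a = e$otu_a, otu_b = e$otu_b,
                           r = e$pearson_r, w = e$z_score,
                           stringsAsFactors = FALSE),
        nEdgesRequested = as.integer(nrow(e)),
        nCandidates = as.integer(nrow(e)), params = list())
}
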