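#' Root Jensen-Shannon divergence between two abundance profiles
#'
#' Restricts both profiles to their shared support (OTUs nonzero in both),
#' renormalizes each over that set, and returns the square root of the
#' Jensen-Shannon divergence of the renormalized profiles: the mean of the
#' two Kullback-Leibler divergences to the midpoint `m = (x + y) / 2`.
#' Logarithms are base 2 by default, so the value lies in \[0, 1\];
#' `sharedSupport = FALSE` switches to the common variant over the union
#' support (zeros contribute nothing, by the convention `0 * log(0/q) = 0`).
#'
#' @param x,y non-negative abundance vectors indexed by the same OTU list.
#' @param base logarithm base (default 2).
#' @param sharedSupport restrict and renormalize to the shared support
#'   (default `TRUE`).
#' @return rJSD distance, 0 iff the renormalized profiles coincide.
#' @export
rjsd <- function(x, y, base = 2, sharedSupport = TRUE) {
    if (length(x) != length(y))
        stop("profiles must have the same length", call. = FALSE)
    if (any(x < 0) || any(y < 0))
        stop("abundances must be non-negative", call. = FALSE)
    if (sharedSupport) {
        s <- x > 0 & y > 0
        if (!any(s))
            stop("no shared OTUs between the two profiles; rJSD undefined",
                 call. = FALSE)
        x <- x[s]
        y <- y[s]
    }
    if (sum(x) == 0 || sum(y) == 0)
        stop("profile with zero total abundance", call. = FALSE)
    x <- x / sum(x)
    y <- y / sum(y)
    m <- (x + y) / 2
    kl <- function(p, q) {
        i <- p > 0
        sum(p[i] * log(p[i] / q[i], base = base))
    }
    sqrt(pmax((kl(x, m) + kl(y, m)) / 2, 0))
}

#' All pairwise rJSD distances between samples
#'
#' @param table a relative-abundance [AbundanceTable-class].
#' @inheritParams rjsd
#' @return symmetric numeric matrix with zero diagonal, dimnames the sample
#'   ids.
#' @export
distanceMatrix <- function(table, base = 2, sharedSupport = TRUE) {
    X <- sampleMatrix(table)
    n <- nrow(X)
    d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
    if (n > 1)
        for (i in seq_len(n - 1))
            for (j in seq(i + 1, n)) {
                d[i, j] <- d[j, i] <- rjsd(X[i, ], X[j, ], base = base,
                                           sharedSupport = sharedSupport)
            }
    d
}

#' Within-group beta diversity
#'
#' All `C(n, 2)` pairwise rJSD distances among the samples of one
#' (group, timepoint) cohort — the distribution summarized by beta-diversity
#' violin plots.
#'
#' @param table a relative-abundance [AbundanceTable-class].
#' @param metadata data.frame with columns `sample_id`, `group`, `timepoint`.
#' @param group,timepoint cohort selector.
#' @return numeric vector of `n(n-1)/2` distances.
#' @export
withinGroupBeta <- function(table, metadata, group, timepoint) {
    ids <- metadata$sample_id[metadata$group == group &
                              metadata$timepoint == timepoint]
    ids <- intersect(sampleIds(table), ids)
    if (length(ids) < 2)
        stop("group needs at least 2 samples for beta diversity",
             call. = FALSE)
    d <- distanceMatrix(table[, ids])
    d[upper.tri(d)]
}

#' Mean rJSD of one sample to a reference cohort
#'
#' @param sample non-negative abundance vector on the reference's OTU list,
#'   or a single-sample [AbundanceTable-class].
#' @param reference a relative-abundance [AbundanceTable-class].
#' @inheritParams rjsd
#' @return mean rJSD from the sample to every reference sample.
#' @export
meanDistanceToReference <- function(sample, reference, base = 2,
                                    sharedSupport = TRUE) {
    if (is(sample, "AbundanceTable")) {
        if (ncol(sample) != 1)
            stop("'sample' must be a single sample", call. = FALSE)
        sample <- abundances(sample)[, 1]
    }
    R <- sampleMatrix(reference)
    if (!nrow(R))
        stop("reference cohort is empty", call. = FALSE)
    mean(apply(R, 1, function(r) rjsd(sample, r, base = base,
                                      sharedSupport = sharedSupport)))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distance matrix is double-centered
#' (Gower), eigendecomposed, and the coordinates along the `nAxes` largest
#' non-negative eigenvalues are returned.  Explained fractions are computed
#' over the positive part of the spectrum; negative eigenvalues (which arise
#' when the distance is not Euclidean-embeddable, as rJSD can be) are
#' dropped and their total magnitude reported.
#'
#' @param d symmetric distance matrix (as from [distanceMatrix()]).
#' @param nAxes number of ordination axes requested (default 2).
#' @return list with `coordinates` (samples x axes), `explained` (fraction
#'   of the positive spectrum per returned axis), `eigenvalues` (full
#'   spectrum) and `negativeMagnitude` (sum of |negative eigenvalues|).
#' @export
pcoa <- function(d, nAxes = 2) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
        stop("distance matrix must be symmetric", call. = FALSE)
    n <- nrow(d)
    fit <- suppressWarnings(
        stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
    ev <- fit$eig
    pos <- which(ev > 1e-9 * max(abs(ev), 1))
    if (nAxes > length(pos)) {
        warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                        length(pos), length(pos)), call. = FALSE)
        nAxes <- length(pos)
    }
    keep <- pos[seq_len(nAxes)]
    coords <- fit$points[, keep, drop = FALSE]
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
    rownames(coords) <- rownames(d)
    list(coordinates = coords,
         explained = ev[keep] / sum(ev[pos]),
         eigenvalues = ev,
         negativeMagnitude = sum(abs(ev[ev < 0])))
}

#' Two-sided Wilcoxon rank-sum test between two sets of values
#'
#' Thin wrapper around [stats::wilcox.test()] used for comparing
#' beta-diversity or network-similarity distributions between groups.
#' Returns 1 when every pooled value is tied (no rank information).
#'
#' @param a,b non-empty numeric vectors.
#' @return two-sided Mann-Whitney/Wilcoxon p-value.
#' @export
rankSumTest <- function(a, b) {
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided")
                     $p.value)
}

#' Per-OTU differential-abundance screen between two cohorts
#'
#' Runs a two-sided Wilcoxon rank-sum test per OTU between the two cohorts'
#' relative abundances and applies Bonferroni correction across OTUs.
#'
#' @param tableA,tableB relative-abundance [AbundanceTable-class] cohorts on
#'   the same OTU set.
#' @return data.frame with columns `otu_id`, `p`, `p_bonferroni`.
#' @export
differentialAbundance <- function(tableA, tableB) {
    if (!identical(otuIds(tableA), otuIds(tableB)))
        stop("cohorts must share one OTU list", call. = FALSE)
    A <- sampleMatrix(tableA)
    B <- sampleMatrix(tableB)
    p <- vapply(seq_len(ncol(A)),
                function(i) rankSumTest(A[, i], B[, i]), numeric(1))
    data.frame(otu_id = otuIds(tableA), p = p,
               p_bonferroni = stats::p.adjust(p, method = "bonferroni"),
               stringsAsFactors = FALSE)
}
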