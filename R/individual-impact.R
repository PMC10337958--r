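#' Direct leave-one-out network impact of one sample
#'
#' Reconstructs the cohort network `B^n` from all samples and `B^(n-k)`
#' without sample k, under identical parameters and seed, and returns the
#' Jaccard dissimilarity `1 - J(B^n, B^(n-k))`.  A value near 0 means the
#' sample follows the cohort's correlation pattern; a value of 1 means its
#' removal produces a completely different network.
#'
#' @param cohort relative-abundance [AbundanceTable-class] with at least 4
#'   samples.
#' @param sampleK sample identifier to leave out.
#' @param netParams list from [networkParams()].
#' @param fullNet optional precomputed cohort network `B^n` (as produced by
#'   `reconstructWithParams` under the same `netParams`); avoids
#'   recomputation in profile loops.
#' @return direct impact in \[0, 1\].
#' @export
directImpact <- function(cohort, sampleK, netParams = networkParams(),
                         fullNet = NULL) {
    if (!sampleK %in% sampleIds(cohort))
        stop("sample '", sampleK, "' is not in the cohort", call. = FALSE)
    if (ncol(cohort) < 4)
        stop("cohort must have at least 4 samples", call. = FALSE)
    bn <- fullNet %||% reconstructWithParams(cohort, netParams)
    bnk <- reconstructWithParams(
        cohort[, setdiff(sampleIds(cohort), sampleK)], netParams)
    1 - jaccardSimilarity(bn, bnk)
}

#' Indirect leave-one-out network impact relative to a reference cohort
#'
#' Measures how removing sample k moves the cohort network towards (or away
#' from) a reference cohort's network:
#' `J(A, B^(n-k)) - J(A, B^n)`, where `A` is the reference network.  A
#' positive value means the cohort becomes more similar to the reference
#' without k, i.e. k is more different from the reference than the rest of
#' its cohort.
#'
#' @inheritParams directImpact
#' @param reference relative-abundance [AbundanceTable-class] of the
#'   reference cohort (must not contain `sampleK`).
#' @param referenceNet optional precomputed reference network.
#' @return indirect impact in \[-1, 1\].
#' @export
indirectImpact <- function(cohort, reference, sampleK,
                           netParams = networkParams(),
                           fullNet = NULL, referenceNet = NULL) {
    if (sampleK %in% sampleIds(reference))
        stop("sample '", sampleK, "' is part of the reference cohort",
             call. = FALSE)
    if (!sampleK %in% sampleIds(cohort))
        stop("sample '", sampleK, "' is not in the cohort", call. = FALSE)
    a <- referenceNet %||% reconstructWithParams(reference, netParams)
    bn <- fullNet %||% reconstructWithParams(cohort, netParams)
    bnk <- reconstructWithParams(
        cohort[, setdiff(sampleIds(cohort), sampleK)], netParams)
    jaccardSimilarity(a, bnk) - jaccardSimilarity(a, bn)
}

#' Leave-one-out impact profile of a whole cohort
#'
#' Runs [directImpact()] (and, when a reference cohort is given,
#' [indirectImpact()]) for every sample of the cohort.  The full-cohort
#' network `B^n` and the reference network are computed once under the
#' shared master seed and reused across all leave-one-out evaluations, so
#' every sample is judged against the same baseline network.  Optionally a
#' one-sided signed-rank outlier p-value ([impactOutlierTest()]) is attached
#' per sample.
#'
#' @inheritParams directImpact
#' @param reference optional reference [AbundanceTable-class]; when `NULL`
#'   the indirect impact is `NA`.
#' @param cohortId label stored in the profile.
#' @param outlierTests logical; attach per-sample signed-rank p-values.
#' @return an [ImpactProfile-class].
#' @export
impactProfile <- function(cohort, reference = NULL,
                          netParams = networkParams(),
                          cohortId = "cohort", outlierTests = FALSE) {
    if (ncol(cohort) < 4)
        stop("cohort must have at least 4 samples", call. = FALSE)
    ids <- sampleIds(cohort)
    bn <- reconstructWithParams(cohort, netParams)
    refNet <- if (!is.null(reference)) {
        overlap <- intersect(ids, sampleIds(reference))
        if (length(overlap))
            stop("cohort sample(s) present in reference: ",
                 paste(overlap, collapse = ", "), call. = FALSE)
        reconstructWithParams(reference, netParams)
    }
    jARef <- if (!is.null(refNet)) jaccardSimilarity(refNet, bn)
    scores <- vapply(ids, function(k) {
        bnk <- reconstructWithParams(cohort[, setdiff(ids, k)], netParams)
        c(direct = 1 - jaccardSimilarity(bn, bnk),
          indirect = if (is.null(refNet)) NA_real_
                     else jaccardSimilarity(refNet, bnk) - jARef)
    }, numeric(2))
    df <- data.frame(sample_id = ids,
                     direct_impact = scores["direct", ],
                     indirect_impact = scores["indirect", ],
                     p_direct = NA_real_, p_indirect = NA_real_,
                     row.names = NULL, stringsAsFactors = FALSE)
    prof <- new("ImpactProfile", cohortId = cohortId, scores = df,
                nEdges = as.integer(netParams$nEdges %||% 500),
                seed = as.integer(netParams$seed %||% 1))
    if (outlierTests) {
        prof@scores$p_direct <- vapply(
            ids, function(k) impactOutlierTest(prof, k, which = "direct"),
            numeric(1))
        if (!is.null(refNet))
            prof@scores$p_indirect <- vapply(
                ids, function(k) impactOutlierTest(prof, k, which = "indirect"),
                numeric(1))
    }
    prof
}

#' @rdname ImpactProfile-accessors
#' @export
setMethod("impactScores", "ImpactProfile", function(x) x@scores)

#' Accessors for ImpactProfile
#'
#' @param x an [ImpactProfile-class].
#' @name ImpactProfile-accessors
#' @aliases impactScores
NULL

setMethod("show", "ImpactProfile", function(object) {
    s <- object@scores
    cat(sprintf("ImpactProfile '%s': %d samples, %d-edge networks, seed %d\n",
                object@cohortId, nrow(s), object@nEdges, object@seed))
    cat(sprintf("  direct impact: median %.3f, max %.3f (%s)\n",
                stats::median(s$direct_impact), max(s$direct_impact),
                s$sample_id[which.max(s$direct_impact)]))
    if (!all(is.na(s$indirect_impact)))
        cat(sprintf("  indirect impact: median %.3f, max %.3f (%s)\n",
                    stats::median(s$indirect_impact), max(s$indirect_impact),
                    s$sample_id[which.max(s$indirect_impact)]))
})

#' Signed-rank test for a single sample's impact being an outlier
#'
#' One-sample Wilcoxon signed-rank test of the differences
#' `score_j - score_k` (over all other samples j) against zero location,
#' one-sided towards sample k having the higher impact.  This is the
#' construction used here to flag individuals whose network impact stands
#' out from the rest of their cohort.
#'
#' @param profile an [ImpactProfile-class] with at least 7 samples (6
#'   others).
#' @param sampleK the sample tested as a potential outlier.
#' @param which `"direct"` or `"indirect"` impact scores.
#' @return one-sided p-value; 1 when all differences are zero.
#' @export
impactOutlierTest <- function(profile, sampleK,
                              which = c("direct", "indirect")) {
    which <- match.arg(which)
    s <- impactScores(profile)
    col <- paste0(which, "_impact")
    if (!sampleK %in% s$sample_id)
        stop("sample '", sampleK, "' is not in the profile", call. = FALSE)
    k <- s[[col]][s$sample_id == sampleK]
    others <- s[[col]][s$sample_id != sampleK]
    if (length(others) < 6)
        stop("need at least 6 other samples for the signed-rank test",
             call. = FALSE)
    d <- others - k
    if (all(d == 0)) return(1)
    # k higher than the others <=> differences located below zero
    suppressWarnings(
        stats::wilcox.test(d, mu = 0, alternative = "less")$p.value)
}

#' Write an impact profile to a tab-separated file
#'
#' @param profile an [ImpactProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImpactProfile <- function(profile, path) {
    utils::write.table(impactScores(profile), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
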