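#' Assemble and validate a workflow configuration
#'
#' Bundles the input paths and every tunable of the full pipeline.  Defaults
#' are the standard study settings: 500-edge networks, W threshold 1, 1000
#' correlation shuffles, 1000 null-network realizations, and OTU filters of
#' 10 total counts and 10% prevalence.
#'
#' @param tablePath path to the OTU count TSV.
#' @param metadataPath path to the sample metadata TSV.
#' @param outDir output directory (created if needed).
#' @param orientation layout of the count table (see [readAbundanceTable()]).
#' @param minTotalCount,minPrevalence OTU filter thresholds.
#' @param nEdges,wThreshold,nShuffles network reconstruction parameters.
#' @param nullRealizations edge-shuffled null ensemble size.
#' @param impactCohort,impactReference optional `"group:timepoint"` labels
#'   selecting the cohort profiled by leave-one-out impact and its reference.
#' @param seed master seed recorded in every artifact.
#' @return validated configuration list of class `"micronetConfig"`.
#' @export
runConfig <- function(tablePath, metadataPath, outDir,
                      orientation = "otus_as_rows",
                      minTotalCount = 10, minPrevalence = 0.10,
                      nEdges = 500, wThreshold = 1.0, nShuffles = 1000,
                      nullRealizations = 1000,
                      impactCohort = NULL, impactReference = NULL,
                      seed = 1) {
    cfg <- list(tablePath = tablePath, metadataPath = metadataPath,
                outDir = outDir, orientation = orientation,
                minTotalCount = minTotalCount, minPrevalence = minPrevalence,
                nEdges = nEdges, wThreshold = wThreshold,
                nShuffles = nShuffles, nullRealizations = nullRealizations,
                impactCohort = impactCohort,
                impactReference = impactReference, seed = seed)
    for (f in c("minTotalCount", "minPrevalence"))
        if (cfg[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
    for (f in c("nEdges", "nShuffles", "nullRealizations"))
        if (cfg[[f]] <= 0) stop(f, " must be positive", call. = FALSE)
    if (cfg$nShuffles < 2) stop("nShuffles must be at least 2", call. = FALSE)
    class(cfg) <- "micronetConfig"
    cfg
}

#' Read a workflow configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()] (snake_case accepted).
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [runConfig()].
#' @return validated configuration list.
#' @export
readRunConfig <- function(path, ...) {
    y <- yaml::read_yaml(path)
    names(y) <- gsub("_(\\w)", "\\U\\1", names(y), perl = TRUE)
    over <- list(...)
    y[names(over)] <- over
    do.call(runConfig, y)
}

wlog <- function(verbose, fmt, ...) {
    if (verbose) message(sprintf("[micronet %s] %s",
                                 format(Sys.time(), "%H:%M:%S"),
                                 sprintf(fmt, ...)))
}

#' Run the full network and community workflow
#'
#' Executes the complete pipeline on one study: read counts and metadata,
#' filter OTUs over the full cohort (so all groups share one OTU set),
#' normalize to relative abundances, split into (group, timepoint) cohorts,
#' reconstruct one fixed-size co-abundance network per cohort, compare every
#' cohort pair against its edge-shuffled null ensemble, optionally profile
#' the leave-one-out network impact of one cohort against a reference, and
#' compute the community-analysis baseline (rJSD distance matrix, per-group
#' beta diversity, PCoA coordinates).  All tables are written as TSV and all
#' summaries as JSON into `outDir`; the configuration and master seed are
#' embedded in the summary so a run can be reproduced from its artifacts.
#'
#' @param config configuration from [runConfig()] or [readRunConfig()].
#' @param verbose log stage progress to stderr.
#' @return (invisibly) list with the networks, comparisons, impact profile,
#'   community results and the paths of all written artifacts.
#' @export
runFullWorkflow <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "micronetConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        r <- tryCatch(expr, error = function(e)
            stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 call. = FALSE))
        wlog(verbose, "%s done in %.1fs", name,
             proc.time()[["elapsed"]] - t0)
        r
    }

    counts <- stage("read", {
        readAbundanceTable(config$tablePath, config$orientation)
    })
    metadata <- stage("metadata", readSampleMetadata(config$metadataPath))
    rel <- stage("preprocess", {
        f <- filterOtus(counts, config$minTotalCount, config$minPrevalence)
        normalizeRelative(f)
    })
    cohorts <- stage("split", splitGroups(rel, metadata))

    netParams <- networkParams(nEdges = config$nEdges,
                               wThreshold = config$wThreshold,
                               nShuffles = config$nShuffles,
                               seed = config$seed)
    nets <- stage("reconstruct", lapply(cohorts, function(tb) {
        if (ncol(tb) >= 3) reconstructWithParams(tb, netParams)
    }))
    nets <- nets[!vapply(nets, is.null, logical(1))]

    paths <- list()
    for (g in names(nets)) {
        p <- file.path(config$outDir,
                       paste0("network_", gsub(":", "_", g), ".tsv"))
        writeEdgeList(nets[[g]], p)
        paths[[paste0("network_", g)]] <- p
    }

    comparisons <- stage("compare", {
        out <- list()
        gs <- names(nets)
        if (length(gs) >= 2)
            for (i in seq_len(length(gs) - 1))
                for (j in seq(i + 1, length(gs))) {
                    key <- paste(gs[i], gs[j], sep = " vs ")
                    out[[key]] <- compareWithNull(
                        nets[[gs[i]]], nets[[gs[j]]],
                        nRealizations = config$nullRealizations,
                        seed = subSeed(config$seed, key))
                }
        out
    })

    impact <- if (!is.null(config$impactCohort)) stage("impact", {
        cohort <- cohorts[[config$impactCohort]]
        if (is.null(cohort))
            stop("impact cohort '", config$impactCohort, "' not found")
        ref <- if (!is.null(config$impactReference))
            cohorts[[config$impactReference]]
        prof <- impactProfile(cohort, ref, netParams,
                              cohortId = config$impactCohort,
                              outlierTests = ncol(cohort) >= 7)
        p <- file.path(config$outDir, "impact_profile.tsv")
        writeImpactProfile(prof, p)
        paths[["impact_profile"]] <- p
        prof
    })

    community <- stage("community", {
        dm <- distanceMatrix(rel)
        dmPath <- file.path(config$outDir, "rjsd_distance_matrix.tsv")
        utils::write.table(
            data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
            dmPath, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[["distance_matrix"]] <- dmPath
        beta <- list()
        for (g in names(cohorts)) {
            gt <- strsplit(g, ":", fixed = TRUE)[[1]]
            if (ncol(cohorts[[g]]) >= 2)
                beta[[g]] <- withinGroupBeta(rel, metadata, gt[1], gt[2])
        }
        betaPath <- file.path(config$outDir, "beta_diversity.tsv")
        utils::write.table(
            do.call(rbind, lapply(names(beta), function(g)
                data.frame(cohort = g, rjsd = beta[[g]]))),
            betaPath, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[["beta_diversity"]] <- betaPath
        ord <- pcoa(dm, nAxes = 2)
        pcPath <- file.path(config$outDir, "pcoa_coordinates.tsv")
        utils::write.table(
            data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates,
                       explained_1 = ord$explained[1],
                       explained_2 = ord$explained[min(2, length(ord$explained))]),
            pcPath, sep = "\t", quote = FALSE, row.names = FALSE)
        paths[["pcoa"]] <- pcPath
        list(distances = dm, beta = beta, pcoa = ord)
    })

    summary <- list(
        config = unclass(config),
        seed = config$seed,
        n_otus_after_filter = length(otuIds(rel)),
        cohort_sizes = vapply(cohorts, ncol, integer(1)),
        networks = lapply(nets, function(n)
            list(n_edges = nEdges(n), shortfall = edgeShortfall(n))),
        comparisons = lapply(comparisons, function(cmp)
            list(jaccard = jaccard(cmp),
                 null_mean = mean(nullJaccards(cmp)),
                 null_sd = stats::sd(nullJaccards(cmp)),
                 p_empirical = pEmpirical(cmp))))
    sumPath <- file.path(config$outDir, "summary.json")
    jsonlite::write_json(summary, sumPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    paths[["summary"]] <- sumPath

    invisible(list(table = rel, cohorts = cohorts, networks = nets,
                   comparisons = comparisons, impact = impact,
                   community = community, paths = paths))
}
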