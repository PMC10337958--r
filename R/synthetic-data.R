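#' Construct a SyntheticCommunitySpec
#'
#' @param nSamples,nOtus cohort dimensions.
#' @param plantedEdges two-column matrix of OTU index pairs to receive
#'   latent correlation `rho`; `NULL` or zero rows plants nothing.
#' @param rho target latent correlation on planted pairs, in (0, 1).
#' @param logMean,logSd log-normal location and scale per OTU (recycled).
#' @param depth sequencing depth, reads per sample (default 50000).
#' @param outliers list of
#'   `list(sample = <index>, mode = "permute"|"foreign", strength = <f>)`;
#'   `"permute"` shuffles the sample's counts across OTU labels (marginal
#'   abundance distribution kept, correlation pattern destroyed), with
#'   `strength` the fraction of OTU labels involved (default 1);
#'   `"foreign"` draws the sample from a rewired planted network with the
#'   same per-OTU marginals.
#' @param seed integer seed.
#' @return a [SyntheticCommunitySpec-class].
#' @export
syntheticCommunitySpec <- function(nSamples, nOtus, plantedEdges = NULL,
                                   rho = 0.9, logMean = 0, logSd = 1,
                                   depth = 50000, outliers = list(),
                                   seed = 1) {
    pe <- if (is.null(plantedEdges)) matrix(integer(), 0, 2)
          else {
              m <- as.matrix(plantedEdges)
              storage.mode(m) <- "integer"
              m
          }
    new("SyntheticCommunitySpec",
        nSamples = as.integer(nSamples), nOtus = as.integer(nOtus),
        plantedEdges = pe, rho = as.numeric(rho),
        logMean = rep_len(as.numeric(logMean), nOtus),
        logSd = rep_len(as.numeric(logSd), nOtus),
        depth = as.integer(depth), outliers = outliers,
        seed = as.integer(seed))
}

#' Random disjoint OTU pairs for planting
#'
#' Draws `nPairs` node-disjoint OTU index pairs; a disjoint set keeps the
#' planted latent correlation matrix positive definite for any `rho < 1`
#' without repair.
#'
#' @param nOtus number of OTUs.
#' @param nPairs number of pairs; at most `floor(nOtus / 2)`.
#' @param seed integer seed.
#' @return two-column integer matrix of index pairs.
#' @export
randomPlantedPairs <- function(nOtus, nPairs, seed = 1) {
    if (2 * nPairs > nOtus)
        stop("cannot place ", nPairs, " disjoint pairs among ", nOtus,
             " OTUs", call. = FALSE)
    withSeed(seed, {
        nodes <- sample.int(nOtus, 2 * nPairs)
        cbind(nodes[seq_len(nPairs)], nodes[nPairs + seq_len(nPairs)])
    })
}

# Dense latent correlation matrix for a planted edge set, repaired to the
# nearest correlation matrix when the naive construction is not positive
# semidefinite.  Errors if the repair moves any planted correlation by more
# than 0.05 — the planted structure would then no longer be the truth.
plantedCorrelation <- function(nOtus, plantedEdges, rho) {
    S <- diag(nOtus)
    if (nrow(plantedEdges)) {
        S[plantedEdges] <- rho
        S[plantedEdges[, c(2, 1), drop = FALSE]] <- rho
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-8) {
            S <- as.matrix(Matrix::nearPD(S, corr = TRUE,
                                          posd.tol = 1e-6)$mat)
            drift <- max(abs(S[plantedEdges] - rho))
            if (drift > 0.05)
                stop(sprintf(paste("correlation repair moved a planted pair",
                                   "by %.3f (> 0.05); use fewer or weaker",
                                   "planted edges"), drift), call. = FALSE)
        }
    }
    S
}

#' Generate a synthetic cohort with planted correlation structure
#'
#' Latent multivariate-normal vectors with the spec's planted correlation
#' matrix are mapped through per-OTU log-normal marginals, closed to
#' relative abundances, and sampled to integer counts by one multinomial
#' draw per sample at the spec's sequencing depth.  Outlier samples are then
#' disrupted according to their mode.  The log-normal/copula construction
#' gives direct control over pairwise association while producing
#' heavy-tailed compositional abundances; the closure and the multinomial
#' resampling attenuate the realized Pearson correlations below `rho`,
#' which is the intended, realistic behaviour.
#'
#' @param spec a [SyntheticCommunitySpec-class].
#' @param otuIds,sampleIds optional identifier vectors (defaults
#'   `OTU_001, ...` and `S001, ...`).
#' @return list with `table` (an [AbundanceTable-class] of counts) and
#'   `truth` (planted edge id pairs, the realized latent correlation matrix,
#'   the outlier list, and the seed).
#' @export
generateCohort <- function(spec, otuIds = NULL, sampleIds = NULL) {
    validObject(spec)
    p <- spec@nOtus
    n <- spec@nSamples
    otuIds <- otuIds %||% sprintf("OTU_%03d", seq_len(p))
    sampleIds <- sampleIds %||% sprintf("S%03d", seq_len(n))
    S <- plantedCorrelation(p, spec@plantedEdges, spec@rho)
    L <- chol(S)
    counts <- withSeed(spec@seed, {
        Z <- matrix(stats::rnorm(n * p), n, p) %*% L
        cnt <- latentToCounts(Z, spec)
        for (o in spec@outliers) {
            s <- o$sample
            mode <- o$mode %||% "permute"
            if (mode == "permute") {
                f <- o$strength %||% 1
                if (f >= 1) {
                    cnt[s, ] <- sample(cnt[s, ])
                } else {
                    # partial disruption: permute only a fraction of labels
                    idx <- sample(p, max(2, round(f * p)))
                    cnt[s, idx] <- cnt[s, idx][sample(length(idx))]
                }
            } else if (mode == "foreign") {
                perm <- sample.int(p)         # rewires the planted edges
                L2 <- chol(S[perm, perm])
                z2 <- matrix(stats::rnorm(p), 1, p) %*% L2
                cnt[s, ] <- latentToCounts(z2, spec)[1, ]
            } else if (mode == "inverted") {
                # sample whose planted correlations are flipped towards
                # -rho: strength 0.5 gives an independent sample, 1 a fully
                # anti-correlated one; marginals are untouched
                lam <- o$strength %||% 1
                Sinv <- plantedCorrelation(p, spec@plantedEdges,
                                           (1 - 2 * lam) * spec@rho)
                z2 <- matrix(stats::rnorm(p), 1, p) %*% chol(Sinv)
                cnt[s, ] <- latentToCounts(z2, spec)[1, ]
            } else stop("unknown outlier mode '", mode, "'", call. = FALSE)
        }
        cnt
    })
    dimnames(counts) <- list(sampleIds, otuIds)
    truth <- list(
        planted_edges = if (nrow(spec@plantedEdges))
            data.frame(otu_a = pmin(otuIds[spec@plantedEdges[, 1]],
                                    otuIds[spec@plantedEdges[, 2]]),
                       otu_b = pmax(otuIds[spec@plantedEdges[, 1]],
                                    otuIds[spec@plantedEdges[, 2]]),
                       stringsAsFactors = FALSE)
            else data.frame(otu_a = character(), otu_b = character()),
        latent_correlation = S,
        outliers = spec@outliers,
        seed = spec@seed)
    list(table = AbundanceTable(t(counts), isRelative = FALSE),
         truth = truth)
}

# latent normal scores -> multinomial counts at fixed depth
latentToCounts <- function(Z, spec) {
    lat <- exp(sweep(sweep(Z, 2, spec@logSd, "*"), 2, spec@logMean, "+"))
    P <- lat / rowSums(lat)
    t(apply(P, 1, function(pr) stats::rmultinom(1, spec@depth, pr)[, 1]))
}

# 9 blocks of 11 nodes among 108 OTUs give 9 * C(11,2) = 495 within-block
# pairs: an equicorrelated-block planted network close to a 500-edge budget
# that stays positive definite for any rho in (0, 1).
blockEdges <- function(blocks) {
    do.call(rbind, lapply(blocks, function(b) {
        if (length(b) < 2) return(matrix(integer(), 0, 2))
        t(utils::combn(b, 2))
    }))
}

#' Four-cohort study fixture at the scale of a two-timepoint 16S study
#'
#' Builds a deterministic synthetic study shaped like a two-group,
#' two-timepoint 16S cohort: 30 + 30 "healthy" and 27 + 27 "gdm" samples
#' over 108 shared OTUs.  The healthy cohorts at both timepoints draw from
#' one planted network of 495 pairs (9 equicorrelated blocks of 11 OTUs).
#' The gdm first-timepoint cohort shares a configurable fraction of those
#' blocks and rewires the rest; the gdm second-timepoint cohort rewires the
#' non-shared blocks again, emulating a perturbation (e.g. a diet
#' intervention) that moves the gdm network away from the reference.
#'
#' @param sharedFraction fraction of the 9 planted blocks shared between the
#'   healthy and gdm networks (default 0.5).
#' @param nHealthy,nGdm subjects per group (defaults 30 and 27).
#' @param rho within-block latent correlation (default 0.6).
#' @param depth sequencing depth (default 30000).
#' @param seed integer master seed.
#' @return list with `tables` (named list of four count
#'   [AbundanceTable-class] objects, names `"healthy:W0"`, ...), `metadata`
#'   (data.frame sample_id / group / timepoint) and `truth` (per-cohort
#'   planted edge tables).
#' @export
simulateStudyCohorts <- function(sharedFraction = 0.5, nHealthy = 30,
                                 nGdm = 27, rho = 0.6, depth = 30000,
                                 seed = 1) {
    stopifnot(sharedFraction >= 0, sharedFraction <= 1)
    p <- 108L
    nodes <- withSeed(subSeed(seed, "partition"), sample.int(p))
    blocks <- split(nodes[seq_len(99)], rep(seq_len(9), each = 11))
    nShared <- round(sharedFraction * 9)
    free <- setdiff(seq_len(p), unlist(blocks[seq_len(nShared)]))
    rewire <- function(s) {
        perm <- withSeed(subSeed(seed, s), sample(free))
        c(blocks[seq_len(nShared)],
          split(perm[seq_len(11 * (9 - nShared))],
                rep(seq_len(9 - nShared), each = 11)))
    }
    edgesets <- list(
        "healthy:W0" = blockEdges(blocks),
        "healthy:W2" = blockEdges(blocks),
        "gdm:W0" = blockEdges(rewire("gdmW0")),
        "gdm:W2" = blockEdges(rewire("gdmW2")))
    sizes <- c("healthy:W0" = nHealthy, "healthy:W2" = nHealthy,
               "gdm:W0" = nGdm, "gdm:W2" = nGdm)
    logMean <- withSeed(subSeed(seed, "marginals"),
                        stats::rnorm(p, mean = 0, sd = 0.5))
    tables <- list()
    truth <- list()
    md <- list()
    for (g in names(edgesets)) {
        gt <- strsplit(g, ":", fixed = TRUE)[[1]]
        prefix <- if (gt[1] == "healthy") "h" else "g"
        ids <- sprintf("%s%02d_%s", prefix, seq_len(sizes[[g]]), gt[2])
        spec <- syntheticCommunitySpec(
            nSamples = sizes[[g]], nOtus = p, plantedEdges = edgesets[[g]],
            rho = rho, logMean = logMean, logSd = 1, depth = depth,
            seed = subSeed(seed, paste0("cohort:", g)))
        out <- generateCohort(spec, sampleIds = ids)
        tables[[g]] <- out$table
        truth[[g]] <- out$truth$planted_edges
        md[[g]] <- data.frame(sample_id = ids, group = gt[1],
                              timepoint = gt[2], stringsAsFactors = FALSE)
    }
    list(tables = tables, metadata = do.call(rbind, c(md, make.row.names = FALSE)),
         truth = truth)
}

#' Combine cohort tables into one study table
#'
#' Column-binds a list of [AbundanceTable-class] objects sharing one OTU
#' list into a single table (e.g. the output of [simulateStudyCohorts()]
#' into the input expected by [splitGroups()]).
#'
#' @param tables named list of [AbundanceTable-class] objects.
#' @return one [AbundanceTable-class].
#' @export
bindCohorts <- function(tables) {
    stopifnot(length(tables) >= 1)
    ref <- otuIds(tables[[1]])
    for (t in tables)
        if (!identical(otuIds(t), ref))
            stop("cohorts must share one OTU list", call. = FALSE)
    AbundanceTable(do.call(cbind, lapply(tables, abundances)),
                   isRelative = isRelative(tables[[1]]))
}

#' Score planted-edge recovery of a reconstructed network
#'
#' Precision and recall of a network's edge set against the generator's
#' planted edge list.
#'
#' @param net a [CoAbundanceNetwork-class].
#' @param plantedEdges data.frame with columns `otu_a`, `otu_b` (as in the
#'   `truth` element of [generateCohort()]).
#' @return named numeric vector with `recall`, `precision`, `n_recovered`.
#' @export
edgeRecovery <- function(net, plantedEdges) {
    truthKeys <- pairKey(plantedEdges$otu_a, plantedEdges$otu_b)
    got <- edgeKeys(net)
    hit <- length(intersect(got, truthKeys))
    c(recall = if (length(truthKeys)) hit / length(truthKeys) else NA_real_,
      precision = if (length(got)) hit / length(got) else NA_real_,
      n_recovered = hit)
}
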