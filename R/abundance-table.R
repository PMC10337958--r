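#' Construct an AbundanceTable
#'
#' @param abundance numeric matrix of non-negative abundances with OTUs as
#'   rows and samples as columns, both dimensions named.
#' @param sampleData optional data.frame (or DataFrame) of per-sample
#'   annotations, typically with columns `group` and `timepoint`; row names
#'   (or a `sample_id` column) must match the sample names.
#' @param isRelative logical; `TRUE` marks the table as relative abundances
#'   (each sample summing to 1), `FALSE` (default) as raw counts.
#'
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("otu1", "otu2"), c("s1", "s2", "s3")))
#' at <- AbundanceTable(m)
#' sampleIds(at)
#' @export
AbundanceTable <- function(abundance, sampleData = NULL, isRelative = FALSE) {
    abundance <- as.matrix(abundance)
    storage.mode(abundance) <- "double"
    cd <- if (is.null(sampleData)) {
        S4Vectors::DataFrame(row.names = colnames(abundance))
    } else {
        sd <- as.data.frame(sampleData)
        if ("sample_id" %in% names(sd) && is.null(rownames(sampleData)))
            rownames(sd) <- sd$sample_id
        sd <- sd[colnames(abundance), , drop = FALSE]
        S4Vectors::DataFrame(sd)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance), colData = cd)
    S4Vectors::metadata(se)$is_relative <- isTRUE(isRelative)
    new("AbundanceTable", se)
}

#' Accessors for AbundanceTable
#'
#' `otuIds` and `sampleIds` return the OTU and sample identifiers, `abundances`
#' the numeric matrix (OTUs as rows by default, samples as rows with
#' `samplesAsRows = TRUE`), and `isRelative` whether the table holds relative
#' abundances.
#'
#' @param x an [AbundanceTable-class].
#' @param samplesAsRows logical; return the transposed samples-by-OTUs matrix.
#' @param ... unused.
#' @name AbundanceTable-accessors
#' @aliases otuIds sampleIds isRelative abundances
NULL

#' @rdname AbundanceTable-accessors
#' @export
setMethod("otuIds", "AbundanceTable", function(x) rownames(x))

#' @rdname AbundanceTable-accessors
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

#' @rdname AbundanceTable-accessors
#' @export
setMethod("isRelative", "AbundanceTable",
    function(x) isTRUE(S4Vectors::metadata(x)$is_relative))

#' @rdname AbundanceTable-accessors
#' @export
setMethod("abundances", "AbundanceTable", function(x, samplesAsRows = FALSE) {
    a <- SummarizedExperiment::assay(x, "abundance")
    if (samplesAsRows) t(a) else a
})

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable: %d OTUs x %d samples (%s)\n",
                nrow(object), ncol(object),
                if (isRelative(object)) "relative abundances" else "counts"))
    if (ncol(SummarizedExperiment::colData(object)))
        cat("sample annotations:",
            paste(names(SummarizedExperiment::colData(object)), collapse = ", "),
            "\n")
})

#' Read an OTU abundance table from a tab-separated file
#'
#' The file must have a header row and identifiers in the first column.
#' Common amplicon exports place OTUs in rows and samples in columns
#' (`orientation = "otus_as_rows"`, the default); the transposed layout is
#' accepted with `orientation = "samples_as_rows"`.
#'
#' @param path path to a TSV file.
#' @param orientation `"otus_as_rows"` or `"samples_as_rows"`.
#' @return an [AbundanceTable-class] of raw counts (`isRelative = FALSE`).
#' @export
readAbundanceTable <- function(path,
                               orientation = c("otus_as_rows",
                                               "samples_as_rows")) {
    orientation <- match.arg(orientation)
    raw <- tryCatch(
        utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE),
        error = function(e) stop("cannot parse '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (!nrow(raw) || ncol(raw) < 2)
        stop("'", path, "' holds no abundance data", call. = FALSE)
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids))
        stop("duplicated identifiers in first column of '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated identifiers in header of '", path, "'", call. = FALSE)
    suppressWarnings(storage.mode(m) <- "double")
    if (any(is.na(m))) {
        bad <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric value at row '%s', column '%s' of '%s'",
                     ids[bad[1]], colnames(m)[bad[2]], path), call. = FALSE)
    }
    if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1, ]
        stop(sprintf("negative value at row '%s', column '%s' of '%s'",
                     ids[bad[1]], colnames(m)[bad[2]], path), call. = FALSE)
    }
    rownames(m) <- ids
    if (orientation == "samples_as_rows") m <- t(m)
    AbundanceTable(m, isRelative = FALSE)
}

#' Write an AbundanceTable to a tab-separated file
#'
#' @param table an [AbundanceTable-class].
#' @param path output path.
#' @param orientation layout of the written file (default OTUs as rows).
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(table, path,
                                orientation = c("otus_as_rows",
                                                "samples_as_rows")) {
    orientation <- match.arg(orientation)
    m <- abundances(table, samplesAsRows = orientation == "samples_as_rows")
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- if (orientation == "otus_as_rows") "otu_id" else "sample_id"
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `group` and `timepoint`.
#'
#' @param path path to a TSV file.
#' @return a data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    md <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "timepoint")
    if (!all(need %in% names(md)))
        stop("metadata must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(md$sample_id))
        stop("duplicated sample_id in metadata", call. = FALSE)
    md
}

#' Filter low-abundance and low-prevalence OTUs
#'
#' Keeps exactly the OTUs whose total count across all samples is at least
#' `minTotalCount` and whose prevalence (fraction of samples with a nonzero
#' count) is at least `minPrevalence`.  Applied to raw counts, before
#' normalization, over the full cohort so that all groups share one OTU set.
#'
#' @param table an [AbundanceTable-class] of raw counts.
#' @param minTotalCount minimum total count across samples (default 10).
#' @param minPrevalence minimum fraction of samples with a nonzero count
#'   (default 0.10).
#' @return the filtered [AbundanceTable-class]; sample set and OTU order are
#'   unchanged.
#' @export
filterOtus <- function(table, minTotalCount = 10, minPrevalence = 0.10) {
    if (isRelative(table))
        stop("filterOtus expects raw counts, not relative abundances",
             call. = FALSE)
    a <- abundances(table)
    keep <- rowSums(a) >= minTotalCount &
        rowMeans(a > 0) >= minPrevalence
    if (!any(keep))
        stop("filtering removed every OTU; relax the thresholds",
             call. = FALSE)
    table[keep, ]
}

#' Normalize each sample to relative abundances
#'
#' Divides every sample's abundance vector by its total so the abundances of
#' each sample sum to one.
#'
#' @param table an [AbundanceTable-class]; every sample must have a positive
#'   total.
#' @return an [AbundanceTable-class] with `isRelative = TRUE`.
#' @export
normalizeRelative <- function(table) {
    a <- abundances(table)
    tot <- colSums(a)
    if (any(tot <= 0))
        stop("sample(s) with zero total abundance: ",
             paste(colnames(a)[tot <= 0], collapse = ", "), call. = FALSE)
    AbundanceTable(sweep(a, 2, tot, "/"),
                   sampleData = as.data.frame(
                       SummarizedExperiment::colData(table)),
                   isRelative = TRUE)
}

#' Split a table into (group, timepoint) cohorts
#'
#' Partitions the samples according to the metadata's `group` and `timepoint`
#' labels.  All resulting tables share the input's OTU set, so networks
#' reconstructed from them live on one common node universe.
#'
#' @param table an [AbundanceTable-class].
#' @param metadata data.frame with columns `sample_id`, `group`, `timepoint`
#'   covering every sample of `table`.
#' @return named list of [AbundanceTable-class] objects, names `"group:timepoint"`.
#' @export
splitGroups <- function(table, metadata) {
    need <- c("sample_id", "group", "timepoint")
    if (!all(need %in% names(metadata)))
        stop("metadata must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    missing <- setdiff(sampleIds(table), metadata$sample_id)
    if (length(missing))
        stop("no metadata for sample(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    md <- metadata[match(sampleIds(table), metadata$sample_id), ]
    key <- paste(md$group, md$timepoint, sep = ":")
    out <- lapply(split(seq_along(key), key), function(i) table[, i])
    out[sort(names(out))]
}
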