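#' @importFrom utils read.delim write.table
NULL

.readTSV <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE,
               quote = "", na.strings = c("NA", ""))
}

#' Read a feature-abundance table from TSV
#'
#' Expects the classic OTU-table layout: first column holds feature
#' identifiers, remaining columns are samples (header row gives sample ids),
#' tab-delimited, `#` comment lines ignored.
#'
#' @param path path to a TSV file.
#' @param kind `"counts"` or `"relative"` (see [FeatureTable()]).
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path, kind = c("counts", "relative")) {
    kind <- match.arg(kind)
    df <- .readTSV(path)
    if (ncol(df) < 2L)
        stop(sprintf("%s: need a feature-id column plus >=1 sample column",
                     path), call. = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop(sprintf("%s: duplicated feature id(s): %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
        stop(sprintf("%s: non-numeric values in column(s): %s", path,
                     paste(names(df)[-1L][bad], collapse = ", ")),
             call. = FALSE)
    }
    rownames(m) <- ids
    FeatureTable(m, kind = kind)
}

#' Write a FeatureTable to TSV
#'
#' Inverse of [readFeatureTable()]; values are written with 10 significant
#' digits so a write/read round trip preserves them to numerical precision.
#'
#' @param x a [FeatureTable-class].
#' @param path output path.
#' @param idColumn name for the feature-id column.
#' @export
writeFeatureTable <- function(x, path, idColumn = "feature_id") {
    stopifnot(is(x, "FeatureTable"))
    m <- abundances(x)
    df <- data.frame(id = rownames(m), signif(m, 10), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- idColumn
    writeRecords(df, path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `group` and `experiment`;
#' `strain_or_cohort` and any number of numeric phenotype columns are
#' optional. Missing phenotype cells become `NA` and are dropped pairwise by
#' the correlation stages.
#'
#' @param path path to a TSV file.
#' @return data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
    df <- .readTSV(path)
    required <- c("sample_id", "group", "experiment")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
        stop(sprintf("%s: missing required column(s): %s", path,
                     paste(missing, collapse = ", ")), call. = FALSE)
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id))
        stop(sprintf("%s: duplicated sample id(s): %s", path,
                     paste(unique(df$sample_id[duplicated(df$sample_id)]),
                           collapse = ", ")), call. = FALSE)
    df
}

#' Write a record table to TSV
#'
#' Deterministic serialization used for every stage output: input column and
#' row order preserved, floats rendered with 10 significant digits,
#' tab-delimited, no quoting.
#'
#' @param records data.frame.
#' @param path output path.
#' @export
writeRecords <- function(records, path) {
    stopifnot(is.data.frame(records))
    out <- records
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], function(v) signif(v, 10))
    dir <- dirname(path)
    if (!dir.exists(dir))
        stop(sprintf("cannot write '%s': directory does not exist", path),
             call. = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' Check that a FeatureTable and metadata describe the same samples
#'
#' Joint analyses fail fast when the sample sets differ; the error lists the
#' set difference in both directions.
#'
#' @param x a [FeatureTable-class].
#' @param meta metadata data.frame with a `sample_id` column.
#' @return invisibly `TRUE` when aligned.
#' @export
checkSampleAlignment <- function(x, meta) {
    s1 <- sampleIds(x); s2 <- meta$sample_id
    onlyTable <- setdiff(s1, s2); onlyMeta <- setdiff(s2, s1)
    if (length(onlyTable) || length(onlyMeta))
        stop(sprintf(
            "sample sets differ: only in table: {%s}; only in metadata: {%s}",
            paste(onlyTable, collapse = ", "),
            paste(onlyMeta, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}
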