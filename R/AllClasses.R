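#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

setOldClass("igraph")

#' FeatureTable: a features-by-samples abundance matrix
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] carrying
#' one `abundance` assay (features in rows, samples in columns) plus a `kind`
#' flag stating whether values are raw counts or per-sample relative
#' abundances (each sample column summing to one).
#'
#' @slot kind either `"counts"` or `"relative"`.
#' @export
setClass("FeatureTable",
    contains = "SummarizedExperiment",
    representation(kind = "character"))

.validFeatureTable <- function(object) {
    msg <- NULL
    if (length(object@kind) != 1L || !object@kind %in% c("counts", "relative"))
        msg <- c(msg, "'kind' must be \"counts\" or \"relative\"")
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        m <- assay(object, "abundance")
        if (!is.numeric(m))
            msg <- c(msg, "abundance values must be numeric")
        else if (any(!is.finite(m)))
            msg <- c(msg, "abundance values must be finite")
        else if (any(m < 0))
            msg <- c(msg, "abundance values must be non-negative")
        if (is.null(rownames(m)) || is.null(colnames(m)))
            msg <- c(msg, "feature and sample identifiers are required")
        else {
            if (anyDuplicated(rownames(m)))
                msg <- c(msg, sprintf("duplicated feature id(s): %s",
                    paste(unique(rownames(m)[duplicated(rownames(m))]),
                          collapse = ", ")))
            if (anyDuplicated(colnames(m)))
                msg <- c(msg, sprintf("duplicated sample id(s): %s",
                    paste(unique(colnames(m)[duplicated(colnames(m))]),
                          collapse = ", ")))
        }
        if (is.numeric(m) && identical(object@kind, "relative") &&
            ncol(m) > 0L) {
            cs <- colSums(m)
            if (any(abs(cs - 1) > 1e-6))
                msg <- c(msg, sprintf(
                    "relative-abundance column(s) not summing to 1: %s",
                    paste(colnames(m)[abs(cs - 1) > 1e-6], collapse = ", ")))
        }
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("FeatureTable", .validFeatureTable)

#' Construct a FeatureTable
#'
#' @param values numeric matrix, features in rows and samples in columns, with
#'   row and column names giving unique feature and sample identifiers.
#' @param kind `"counts"` for raw read counts, `"relative"` for per-sample
#'   proportions (columns must sum to one).
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 4, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("otuA", "otuB"), c("s1", "s2", "s3")))
#' ft <- FeatureTable(m, kind = "counts")
#' featureIds(ft)
#' @export
FeatureTable <- function(values, kind = c("counts", "relative")) {
    kind <- match.arg(kind)
    if (!is.matrix(values))
        values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = SimpleList(abundance = values))
    new("FeatureTable", se, kind = kind)
}

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable (%s): %d features x %d samples\n",
                object@kind, nrow(object), ncol(object)))
    invisible(NULL)
})

#' GeneNetwork: an undirected gene co-expression network
#'
#' Built by [buildNetwork()] from per-group correlations that pass the edge
#' admissibility criteria. Nodes are genes with at least one admissible edge;
#' per-node attributes include the log2 fold change, degree and average
#' shortest path length.
#'
#' @slot graph an [igraph::igraph] simple undirected graph.
#' @slot nodes data.frame with columns `gene`, `log2_fc`, `degree`,
#'   `avg_shortest_path`.
#' @slot edges data.frame with one row per admissible edge (`gene_a`,
#'   `gene_b`, `sign`, per-group correlations, `p_combined`).
#' @slot membershipFraction fraction of candidate genes retained as nodes.
#' @slot params list of thresholds used.
#' @export
setClass("GeneNetwork",
    representation(graph = "igraph", nodes = "data.frame",
                   edges = "data.frame", membershipFraction = "numeric",
                   params = "list"))

.validGeneNetwork <- function(object) {
    msg <- NULL
    g <- object@graph
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g)))
        msg <- c(msg, "graph must have no self-loops")
    if (igraph::any_multiple(g))
        msg <- c(msg, "graph must be simple (no multi-edges)")
    if (igraph::vcount(g) != nrow(object@nodes))
        msg <- c(msg, "node table does not match graph vertex count")
    if (igraph::ecount(g) != nrow(object@edges))
        msg <- c(msg, "edge table does not match graph edge count")
    if (nrow(object@edges) > 0 &&
        any(object@edges$gene_a == object@edges$gene_b))
        msg <- c(msg, "edge table contains a self-loop")
    if (is.null(msg)) TRUE else msg
}

setValidity("GeneNetwork", .validGeneNetwork)

setMethod("show", "GeneNetwork", function(object) {
    cat(sprintf(
        "GeneNetwork: %d nodes, %d edges (membership %.1f%% of %d candidates)\n",
        igraph::vcount(object@graph), igraph::ecount(object@graph),
        100 * object@membershipFraction,
        round(igraph::vcount(object@graph) /
              max(object@membershipFraction, .Machine$double.eps))))
    invisible(NULL)
})
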