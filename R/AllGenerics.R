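#' @rdname FeatureTable
#' @param x a `FeatureTable` or `GeneNetwork`.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureTable
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureTable
#' @export
setGeneric("abundanceKind", function(x) standardGeneric("abundanceKind"))

#' @rdname FeatureTable
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname GeneNetwork-class
#' @param x a `GeneNetwork`.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("membershipFraction",
    function(x) standardGeneric("membershipFraction"))

#' @rdname FeatureTable
#' @export
setMethod("featureIds", "FeatureTable", function(x) rownames(x))

#' @rdname FeatureTable
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

#' @rdname FeatureTable
#' @export
setMethod("abundanceKind", "FeatureTable", function(x) x@kind)

#' @rdname FeatureTable
#' @export
setMethod("abundances", "FeatureTable",
    function(x) SummarizedExperiment::assay(x, "abundance"))

#' @rdname GeneNetwork-class
#' @export
setMethod("networkGraph", "GeneNetwork", function(x) x@graph)

#' @rdname GeneNetwork-class
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname GeneNetwork-class
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

#' @rdname GeneNetwork-class
#' @export
setMethod("membershipFraction", "GeneNetwork",
    function(x) x@membershipFraction)
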