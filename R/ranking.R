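#' Signed absolute average correlation across groups
#'
#' Ranking sources s1 and s4: s1 is the absolute value of the mean per-group
#' correlation between a gene and the target microbe; s4 carries a positive
#' sign when the per-group correlations share the same (nonzero) sign in all
#' groups and a negative sign otherwise, so directionally consistent genes
#' outrank inconsistent ones of equal magnitude.
#'
#' @param rhos numeric vector of per-group correlation coefficients (>= 2
#'   groups, all within `[-1, 1]`, no missing values).
#' @return list with `s1` (\eqn{|mean(rhos)|}), `s4` (signed s1) and
#'   `direction_class` (`putative_inhibitor` when the shared sign is
#'   negative, `putative_enhancer` when positive, otherwise
#'   `inconsistent`; exact zeros count as inconsistent).
#' @examples
#' signedAbsAvgCorrelation(c(-0.5, -0.4, -0.6))
#' @export
signedAbsAvgCorrelation <- function(rhos) {
    .checkNumericVector(rhos, "rhos")
    if (length(rhos) < 2L)
        stop("need correlations from at least 2 groups", call. = FALSE)
    if (any(abs(rhos) > 1))
        stop("correlation coefficients must lie in [-1, 1]", call. = FALSE)
    s1 <- abs(mean(rhos))
    consistent <- all(rhos > 0) || all(rhos < 0)
    s4 <- if (consistent) s1 else -s1
    cls <- if (!consistent) "inconsistent"
           else if (rhos[1L] < 0) "putative_inhibitor"
           else "putative_enhancer"
    list(s1 = s1, s4 = s4, direction_class = cls)
}

#' Four-source rank-sum score
#'
#' Core arithmetic of the regulator prioritization, exposed separately so it
#' can be applied to any source table. Each source column is ranked
#' ascending (smallest value = rank 1, average ties); the four ranks are
#' summed; genes are ordered by descending total (larger totals = stronger
#' candidates, since e.g. longer average path lengths rank higher), with the
#' gene id as deterministic tiebreak; `final_rank` 1 is the top candidate.
#'
#' @param sources data.frame with columns `gene_id`, `s1_abs_avg_corr`,
#'   `s2_avg_shortest_path`, `s3_abs_log10_fc`, `s4_signed_abs_avg_corr`.
#' @return the input with rank columns `r1`..`r4`, `total_score` and
#'   `final_rank` appended, sorted by `final_rank`.
#' @export
scoreRegulators <- function(sources) {
    need <- c("gene_id", "s1_abs_avg_corr", "s2_avg_shortest_path",
              "s3_abs_log10_fc", "s4_signed_abs_avg_corr")
    miss <- setdiff(need, names(sources))
    if (length(miss))
        stop(sprintf("missing source column(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    out <- sources
    out$r1 <- rankAscending(out$s1_abs_avg_corr)
    out$r2 <- rankAscending(out$s2_avg_shortest_path)
    out$r3 <- rankAscending(out$s3_abs_log10_fc)
    out$r4 <- rankAscending(out$s4_signed_abs_avg_corr)
    out$total_score <- out$r1 + out$r2 + out$r3 + out$r4
    ord <- order(-out$total_score, out$gene_id)
    out <- out[ord, , drop = FALSE]
    out$final_rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Prioritize host genes as regulators of a target microbe
#'
#' Integrates four sources of evidence for every network-member gene:
#' s1, the absolute average per-group Pearson correlation between the gene's
#' expression and the microbe's abundance; s2, the gene's average shortest
#' path length in the co-expression network (peripheral genes score
#' higher); s3, the absolute log10 fold change versus control; s4, s1 signed
#' by cross-group directional consistency. Each source is ranked ascending
#' with average ties and the ranks are summed; the gene with the largest
#' total is the top candidate (`final_rank` 1). Genes sharing a consistent
#' negative correlation with the microbe are labelled putative inhibitors.
#'
#' @param network a [GeneNetwork-class]; only its member genes are ranked.
#' @param exprGroups named list of expression matrices (genes x samples),
#'   one per group of perturbed-genotype samples.
#' @param microbeByGroup named list (same names) of per-sample microbe
#'   abundance vectors aligned with each matrix's columns.
#' @param foldChanges named numeric vector of log2 fold changes (perturbed
#'   versus control); converted internally to the log10 scale for s3.
#' @param fcScale scale of `foldChanges`: `"log2"` (default) or `"log10"`.
#' @return data.frame of rank records sorted by `final_rank`: gene id, the
#'   four source values, `r1`..`r4`, `total_score`, `final_rank` and
#'   `direction_class`.
#' @export
prioritizeRegulators <- function(network, exprGroups, microbeByGroup,
                                 foldChanges, fcScale = c("log2", "log10")) {
    fcScale <- match.arg(fcScale)
    stopifnot(is(network, "GeneNetwork"))
    if (!identical(sort(names(exprGroups)), sort(names(microbeByGroup))))
        stop("'exprGroups' and 'microbeByGroup' must share group names",
             call. = FALSE)
    for (gname in names(exprGroups)) {
        if (ncol(exprGroups[[gname]]) != length(microbeByGroup[[gname]]))
            stop(sprintf(
                "group '%s': expression samples and microbe abundances differ",
                gname), call. = FALSE)
    }
    nodes <- networkNodes(network)
    genes <- nodes$gene[!is.na(nodes$avg_shortest_path)]
    dropped <- setdiff(nodes$gene, genes)
    if (length(dropped))
        warning(sprintf("gene(s) without defined path length excluded: %s",
                        paste(dropped, collapse = ", ")))
    shared <- Reduce(intersect, lapply(exprGroups, rownames))
    noExpr <- setdiff(genes, shared)
    if (length(noExpr)) {
        warning(sprintf("network gene(s) without expression excluded: %s",
                        paste(noExpr, collapse = ", ")))
        genes <- setdiff(genes, noExpr)
    }
    if (length(genes) == 0L)
        stop("no rankable genes", call. = FALSE)
    k <- length(exprGroups)
    rmat <- matrix(NA_real_, length(genes), k,
                   dimnames = list(genes, names(exprGroups)))
    for (gname in names(exprGroups)) {
        m <- exprGroups[[gname]][genes, , drop = FALSE]
        ab <- microbeByGroup[[gname]]
        rmat[, gname] <- suppressWarnings(
            as.vector(cor(t(m), ab)))
    }
    if (anyNA(rmat))
        stop("undefined gene-microbe correlation (constant vector?)",
             call. = FALSE)
    sig <- t(apply(rmat, 1L, function(rh) {
        s <- signedAbsAvgCorrelation(rh)
        c(s1 = s$s1, s4 = s$s4)
    }))
    cls <- apply(rmat, 1L, function(rh)
        signedAbsAvgCorrelation(rh)$direction_class)
    lfc <- foldChanges[genes]
    s3 <- if (fcScale == "log2") abs(lfc) * log10(2) else abs(lfc)
    sources <- data.frame(
        gene_id = genes,
        s1_abs_avg_corr = unname(sig[, "s1"]),
        s2_avg_shortest_path =
            nodes$avg_shortest_path[match(genes, nodes$gene)],
        s3_abs_log10_fc = unname(s3),
        s4_signed_abs_avg_corr = unname(sig[, "s4"]),
        stringsAsFactors = FALSE)
    out <- scoreRegulators(sources)
    out$direction_class <- cls[out$gene_id]
    rownames(out) <- NULL
    out
}
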