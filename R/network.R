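#' Per-group gene-gene correlations with Fisher-combined p values
#'
#' For every gene pair, the Pearson correlation and two-sided p value are
#' computed separately within each sample group (e.g. mouse strains), the k
#' per-group p values are merged with Fisher's combined probability test
#' (chi-squared with 2k degrees of freedom), and an FDR is attached across
#' all evaluated pairs. Pairs involving a gene that is constant within any
#' group are flagged untestable.
#'
#' @param exprGroups named list of k numeric matrices (genes x samples, >= 3
#'   samples each) sharing the same row (gene) names.
#' @param genes optional subset of genes to evaluate (default: all shared
#'   genes).
#' @return data.frame with one row per unordered pair: `gene_a`, `gene_b`,
#'   `r_<group>` and `p_<group>` per group, `chi2`, `p_combined`, `q`,
#'   `testable`.
#' @export
perGroupCorrelations <- function(exprGroups, genes = NULL) {
    stopifnot(is.list(exprGroups), length(exprGroups) >= 1L)
    if (is.null(names(exprGroups)))
        names(exprGroups) <- paste0("g", seq_along(exprGroups))
    gsets <- lapply(exprGroups, rownames)
    shared <- Reduce(intersect, gsets)
    if (is.null(genes)) genes <- shared
    missing <- setdiff(genes, shared)
    if (length(missing))
        stop(sprintf("gene(s) absent from some group: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    if (length(genes) < 2L)
        stop("need at least 2 genes", call. = FALSE)
    ns <- vapply(exprGroups, ncol, integer(1))
    if (any(ns < 3L))
        stop("every group needs >= 3 samples", call. = FALSE)
    k <- length(exprGroups)
    nG <- length(genes)
    idx <- which(upper.tri(matrix(0, nG, nG)), arr.ind = TRUE)
    rmat <- matrix(NA_real_, nrow(idx), k)
    pmat <- matrix(NA_real_, nrow(idx), k)
    constAny <- rep(FALSE, nG)
    for (j in seq_len(k)) {
        m <- exprGroups[[j]][genes, , drop = FALSE]
        sds <- apply(m, 1L, sd)
        constAny <- constAny | sds == 0
        cc <- suppressWarnings(cor(t(m)))
        rmat[, j] <- cc[idx]
        pmat[, j] <- .corrPvalue(rmat[, j], ns[j])
    }
    testable <- !(constAny[idx[, 1L]] | constAny[idx[, 2L]])
    out <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
        out[[paste0("r_", names(exprGroups)[j])]] <- rmat[, j]
        out[[paste0("p_", names(exprGroups)[j])]] <- pmat[, j]
    }
    chi2 <- rep(NA_real_, nrow(idx))
    pcomb <- rep(NA_real_, nrow(idx))
    if (any(testable)) {
        fc <- .fisherCombinedRows(pmat[testable, , drop = FALSE])
        chi2[testable] <- fc$chi2
        pcomb[testable] <- fc$p_combined
    }
    out$chi2 <- chi2
    out$p_combined <- pcomb
    out$q <- bhFDR(pcomb)
    out$testable <- testable
    out
}

#' Edge admissibility for the gene network
#'
#' A gene pair becomes an edge only when (1) the within-group correlation p
#' value is below `pInd` in every group, (2) the Fisher-combined p value is
#' below `pComb`, (3) the correlation signs agree (all positive or all
#' negative) across groups, and (4) the shared correlation sign is
#' consistent with the genes' fold-change relationship: co-regulated genes
#' (fold changes in the same direction) must correlate positively,
#' oppositely regulated genes negatively, i.e.
#' `sign(r) == sign(lfcA * lfcB)`.
#'
#' @param r,p numeric vectors of per-group correlations and p values.
#' @param pCombined Fisher-combined p value of `p`.
#' @param lfcA,lfcB the two genes' (log) fold changes versus control.
#' @param pInd per-group p threshold (default 0.3).
#' @param pComb combined p threshold (default 0.01).
#' @return logical.
#' @export
edgeAdmissible <- function(r, p, pCombined, lfcA, lfcB,
                           pInd = 0.3, pComb = 0.01) {
    if (anyNA(r) || anyNA(p) || is.na(pCombined)) return(FALSE)
    signsOk <- all(r > 0) || all(r < 0)
    if (!signsOk) return(FALSE)
    all(p < pInd) && pCombined < pComb &&
        sign(r[1L]) == sign(lfcA * lfcB) && lfcA * lfcB != 0
}

# Vectorised admissibility over the pair table from perGroupCorrelations().
.admissiblePairs <- function(pc, foldChanges, pInd, pComb) {
    rcols <- names(pc)[startsWith(names(pc), "r_")]
    pcols <- paste0("p_", substring(rcols, 3L))
    k <- length(rcols)
    rmat <- as.matrix(pc[rcols])
    pmat <- as.matrix(pc[pcols])
    lfcA <- foldChanges[pc$gene_a]
    lfcB <- foldChanges[pc$gene_b]
    allPos <- rowSums(rmat > 0) == k
    allNeg <- rowSums(rmat < 0) == k
    sgn <- ifelse(allPos, 1, ifelse(allNeg, -1, 0))
    pc$testable &
        rowSums(pmat < pInd) == k &
        !is.na(pc$p_combined) & pc$p_combined < pComb &
        sgn != 0 &
        sgn == sign(lfcA * lfcB) & lfcA * lfcB != 0
}

#' Reconstruct the gene co-expression network
#'
#' Evaluates all pairs of `geneSubset` (typically the differential-expression
#' signature) with [perGroupCorrelations()], keeps admissible pairs as edges
#' (see [edgeAdmissible()]), and returns genes with at least one edge as
#' network members, together with per-node degree and average shortest path
#' length.
#'
#' @inheritParams perGroupCorrelations
#' @param foldChanges named numeric vector of log2 fold changes (perturbed
#'   versus control) covering `geneSubset`.
#' @param geneSubset genes to consider (default: all shared genes).
#' @param pInd,pComb edge thresholds, see [edgeAdmissible()].
#' @return A [GeneNetwork-class].
#' @export
buildNetwork <- function(exprGroups, foldChanges, geneSubset = NULL,
                         pInd = 0.3, pComb = 0.01) {
    if (is.null(geneSubset))
        geneSubset <- Reduce(intersect, lapply(exprGroups, rownames))
    geneSubset <- sort(geneSubset)
    if (length(geneSubset) < 2L)
        stop("gene subset must contain at least 2 genes", call. = FALSE)
    missFc <- setdiff(geneSubset, names(foldChanges))
    if (length(missFc))
        stop(sprintf("fold change missing for gene(s): %s",
                     paste(missFc, collapse = ", ")), call. = FALSE)
    pc <- perGroupCorrelations(exprGroups, genes = geneSubset)
    adm <- .admissiblePairs(pc, foldChanges, pInd, pComb)
    edges <- pc[adm, , drop = FALSE]
    rcols <- startsWith(names(edges), "r_")
    edges$sign <- if (nrow(edges)) {
        ifelse(rowSums(as.matrix(edges[rcols]) > 0) == sum(rcols), 1L, -1L)
    } else integer(0)
    edges$q <- NULL
    edges$testable <- NULL
    rownames(edges) <- NULL
    g <- igraph::graph_from_data_frame(
        edges[, c("gene_a", "gene_b"), drop = FALSE], directed = FALSE,
        vertices = data.frame(name = geneSubset, stringsAsFactors = FALSE))
    keep <- igraph::V(g)[igraph::degree(g) > 0]
    g <- igraph::induced_subgraph(g, keep)
    members <- igraph::V(g)$name
    nodes <- data.frame(
        gene = members,
        log2_fc = unname(foldChanges[members]),
        degree = igraph::degree(g),
        avg_shortest_path = .avgPathAll(g),
        stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    new("GeneNetwork", graph = g, nodes = nodes, edges = edges,
        membershipFraction = length(members) / length(geneSubset),
        params = list(pInd = pInd, pComb = pComb))
}

# Mean unweighted shortest-path distance from each vertex to the other
# vertices of its connected component (NA for isolated vertices).
.avgPathAll <- function(g) {
    if (igraph::vcount(g) == 0L) return(numeric(0))
    d <- igraph::distances(g, algorithm = "unweighted")
    diag(d) <- NA
    d[is.infinite(d)] <- NA
    out <- rowMeans(d, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    unname(out)
}

#' Average shortest path length of a node
#'
#' Mean unweighted (hop-count) shortest-path distance from `node` to every
#' other gene in its connected component. Large values mark peripheral
#' genes; this is ranking source s2 of [prioritizeRegulators()].
#'
#' @param g a [GeneNetwork-class].
#' @param node gene id, must be a network member.
#' @return numeric scalar; `NA` for an isolated node (such nodes are
#'   excluded from ranking).
#' @export
avgShortestPathLength <- function(g, node) {
    stopifnot(is(g, "GeneNetwork"))
    graph <- networkGraph(g)
    if (!node %in% igraph::V(graph)$name)
        stop(sprintf("gene '%s' is not a network member", node),
             call. = FALSE)
    if (igraph::degree(graph, node) == 0L) return(NA_real_)
    d <- igraph::distances(graph, v = node, algorithm = "unweighted")
    d <- d[1L, setdiff(colnames(d), node)]
    mean(d[is.finite(d)])
}
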