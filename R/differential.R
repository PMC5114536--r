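#' Convert a counts FeatureTable to relative abundances
#'
#' Each sample column is divided by its total read count, mirroring
#' total-sum normalization of OTU tables.
#'
#' @param x a counts [FeatureTable-class] with no all-zero sample column.
#' @return a `"relative"` [FeatureTable-class]; column sums are 1 to within
#'   1e-12.
#' @export
toRelativeAbundance <- function(x) {
    stopifnot(is(x, "FeatureTable"))
    if (abundanceKind(x) != "counts")
        stop("input must be a counts table", call. = FALSE)
    m <- abundances(x)
    cs <- colSums(m)
    if (any(cs == 0))
        stop(sprintf("all-zero sample column(s): %s",
                     paste(colnames(m)[cs == 0], collapse = ", ")),
             call. = FALSE)
    FeatureTable(sweep(m, 2L, cs, "/"), kind = "relative")
}

#' Differentially abundant features between two groups
#'
#' Per-feature two-group test (Welch by default) of perturbed versus control
#' samples, with Benjamini-Hochberg FDR across all features of the table.
#' The test runs on `log2(relative abundance + pseudocount)` by default; the
#' pseudocount is half the smallest nonzero relative abundance of the table.
#' Features that are constant across all samples are flagged `degenerate`
#' with missing p/q.
#'
#' @param x a relative-abundance [FeatureTable-class] (a counts table is
#'   normalized automatically).
#' @param meta metadata data.frame with `sample_id` and `group` columns
#'   covering the table's samples.
#' @param perturbedLabel,controlLabel group labels to compare; each group
#'   needs >= 2 samples.
#' @param logTransform test on log2-transformed abundances (default) or raw.
#' @param pseudocount pseudocount added before the log; `NULL` picks half
#'   the smallest nonzero value in the table.
#' @param varEqual pooled-variance instead of Welch test.
#' @return data.frame with one row per feature: `feature_id`,
#'   `mean_perturbed`, `mean_control` (relative-abundance scale),
#'   `direction` (+1/-1, sign of perturbed - control), `log2_fc`, `p`, `q`,
#'   `degenerate`.
#' @export
differentialFeatures <- function(x, meta, perturbedLabel, controlLabel,
                                 logTransform = TRUE, pseudocount = NULL,
                                 varEqual = FALSE) {
    stopifnot(is(x, "FeatureTable"))
    if (abundanceKind(x) == "counts")
        x <- toRelativeAbundance(x)
    if (!all(c("sample_id", "group") %in% names(meta)))
        stop("metadata needs 'sample_id' and 'group' columns", call. = FALSE)
    m <- abundances(x)
    meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
    sPert <- meta$sample_id[meta$group == perturbedLabel]
    sCtrl <- meta$sample_id[meta$group == controlLabel]
    if (length(sPert) < 2L || length(sCtrl) < 2L)
        stop(sprintf(
            "need >= 2 samples per group (perturbed '%s': %d, control '%s': %d)",
            perturbedLabel, length(sPert), controlLabel, length(sCtrl)),
            call. = FALSE)
    a <- m[, sPert, drop = FALSE]
    b <- m[, sCtrl, drop = FALSE]
    if (is.null(pseudocount)) {
        nz <- m[m > 0]
        pseudocount <- if (length(nz)) min(nz) / 2 else 0.5
    }
    ta <- a; tb <- b
    if (logTransform) {
        ta <- log2(a + pseudocount)
        tb <- log2(b + pseudocount)
    }
    w <- .rowWelch(ta, tb)
    if (varEqual) {   # pooled-variance variant goes feature-by-feature
        for (i in which(!w$degenerate)) {
            ht <- t.test(ta[i, ], tb[i, ], var.equal = TRUE)
            w$statistic[i] <- unname(ht$statistic)
            w$p_value[i] <- ht$p.value
            w$df[i] <- unname(ht$parameter)
        }
    }
    meanP <- rowMeans(a); meanC <- rowMeans(b)
    res <- data.frame(
        feature_id = rownames(m),
        mean_perturbed = meanP,
        mean_control = meanC,
        direction = sign(meanP - meanC),
        log2_fc = log2((meanP + pseudocount) / (meanC + pseudocount)),
        p = w$p_value,
        q = bhFDR(w$p_value),
        degenerate = w$degenerate,
        stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Direction-concordant features across two perturbation experiments
#'
#' A feature is concordant when it passes the FDR threshold in both
#' experiments with the same direction of change — the criterion used to
#' call a taxon "regulated" by the perturbed factor rather than by
#' experiment-specific confounders.
#'
#' @param resA,resB outputs of [differentialFeatures()] for the two
#'   experiments.
#' @param tau FDR threshold (default 0.1).
#' @return data.frame over the feature intersection: `feature_id`,
#'   `direction_A`, `direction_B`, `q_A`, `q_B`, `concordant`.
#' @export
concordantFeatures <- function(resA, resB, tau = 0.1) {
    common <- intersect(resA$feature_id, resB$feature_id)
    a <- resA[match(common, resA$feature_id), ]
    b <- resB[match(common, resB$feature_id), ]
    out <- data.frame(
        feature_id = common,
        direction_A = a$direction,
        direction_B = b$direction,
        q_A = a$q,
        q_B = b$q,
        stringsAsFactors = FALSE)
    out$concordant <- !is.na(out$q_A) & !is.na(out$q_B) &
        out$q_A < tau & out$q_B < tau &
        out$direction_A == out$direction_B & out$direction_A != 0
    rownames(out) <- NULL
    out
}
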