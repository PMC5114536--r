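#' Select samples in which a feature is sufficiently abundant
#'
#' The cohort-style filter: keep only samples where the feature's relative
#' abundance reaches `minAbund`, so that correlation with a phenotype is
#' assessed where the microbe is plausibly a player.
#'
#' @param x a relative-abundance [FeatureTable-class].
#' @param featureId feature to filter on.
#' @param minAbund minimum relative abundance (default 0.01, i.e. 1%).
#' @return character vector of sample ids.
#' @export
selectSamplesByFeature <- function(x, featureId, minAbund = 0.01) {
    stopifnot(is(x, "FeatureTable"))
    m <- abundances(x)
    if (!featureId %in% rownames(m))
        stop(sprintf("unknown feature: '%s'", featureId), call. = FALSE)
    colnames(m)[m[featureId, ] >= minAbund]
}

#' Correlate feature abundances with phenotypes
#'
#' For each feature x phenotype pair, the correlation (Spearman by default,
#' matching the use for taxa) over pairwise-complete observations, with
#' two-sided p and the effective n recorded. Pairs with fewer than 3
#' complete observations are flagged untestable instead of erroring.
#'
#' @param x a [FeatureTable-class].
#' @param meta metadata data.frame with `sample_id` and the phenotype
#'   columns.
#' @param features feature ids to test (default: all).
#' @param phenotypes names of phenotype columns in `meta`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with `feature_id`, `phenotype`, `rho`, `p`, `n`,
#'   `testable`.
#' @export
phenotypeCorrelations <- function(x, meta, features = NULL, phenotypes,
                                  method = c("spearman", "pearson")) {
    method <- match.arg(method)
    stopifnot(is(x, "FeatureTable"))
    m <- abundances(x)
    if (is.null(features)) features <- rownames(m)
    missF <- setdiff(features, rownames(m))
    if (length(missF))
        stop(sprintf("unknown feature(s): %s", paste(missF, collapse = ", ")),
             call. = FALSE)
    missP <- setdiff(phenotypes, names(meta))
    if (length(missP))
        stop(sprintf("phenotype column(s) absent from metadata: %s",
                     paste(missP, collapse = ", ")), call. = FALSE)
    meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
    res <- vector("list", length(features) * length(phenotypes))
    i <- 0L
    for (f in features) {
        ab <- m[f, meta$sample_id]
        for (ph in phenotypes) {
            y <- meta[[ph]]
            keep <- !is.na(ab) & !is.na(y)
            i <- i + 1L
            if (sum(keep) < 3L || sd(ab[keep]) == 0 || sd(y[keep]) == 0) {
                res[[i]] <- data.frame(feature_id = f, phenotype = ph,
                                       rho = NA_real_, p = NA_real_,
                                       n = sum(keep), testable = FALSE,
                                       stringsAsFactors = FALSE)
            } else {
                ct <- .corrTest(ab[keep], y[keep], method)
                res[[i]] <- data.frame(feature_id = f, phenotype = ph,
                                       rho = ct$statistic, p = ct$p_value,
                                       n = sum(keep), testable = TRUE,
                                       stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, res)
}

#' Nominate phenotype mediators among perturbation-regulated features
#'
#' Implements the sign-matching causal screen: a regulated feature is a
#' candidate mediator only when the direction of its regulation by the
#' factor matches the sign of its within-perturbed-group correlation with
#' every phenotype. With the factor removed in the perturbed group (the
#' default, as in a knockout), a feature that is UP in the perturbed group
#' is depleted by the factor; if such a feature correlates negatively with
#' the adverse phenotype it is a `candidate_improver`. A feature DOWN in the
#' perturbed group is enriched by the factor; consistent positive
#' correlations make it a `candidate_worsener`. Everything else is
#' `not_candidate`.
#'
#' Correlations must have been computed within the perturbed group only, so
#' that direct effects of the factor cannot bias them; supplying `meta` and
#' `controlLabel` lets the function verify this and refuse contaminated
#' input.
#'
#' @param concord output of [concordantFeatures()]; only concordant features
#'   are screened.
#' @param corr output of [phenotypeCorrelations()] computed on
#'   perturbed-group samples.
#' @param alpha per-phenotype correlation p cutoff (default 0.05).
#' @param requireAll `TRUE` (default): every phenotype must pass the sign
#'   rule; `FALSE`: any one suffices (correlation signs must still agree
#'   across phenotypes).
#' @param factorRemoved `TRUE` when the perturbed group lacks the factor
#'   (knockout/blockade design), so direction +1 means depleted-by-factor.
#' @param meta,controlLabel optional metadata of the samples used for
#'   `corr`; if the control label occurs in its `group` column the function
#'   stops.
#' @return data.frame ordered by minimum p across phenotypes (feature id as
#'   tiebreak): `feature_id`, `regulation_direction`, per-phenotype `rho_*`
#'   and `p_*` columns, `min_p`, `classification`.
#' @export
nominateMediators <- function(concord, corr, alpha = 0.05,
                              requireAll = TRUE, factorRemoved = TRUE,
                              meta = NULL, controlLabel = NULL) {
    if (!is.null(meta) && !is.null(controlLabel) &&
        controlLabel %in% meta$group)
        stop(sprintf(
            "correlation metadata contains control-group label '%s'; %s",
            controlLabel,
            "mediator correlations must be restricted to the perturbed group"),
            call. = FALSE)
    kept <- concord$feature_id[concord$concordant]
    orphan <- setdiff(unique(corr$feature_id), concord$feature_id)
    if (length(orphan))
        warning(sprintf(
            "feature(s) with correlations but absent from concordance: %s",
            paste(orphan, collapse = ", ")))
    corr <- corr[corr$feature_id %in% kept, , drop = FALSE]
    feats <- intersect(kept, unique(corr$feature_id))
    if (length(feats) == 0L) {
        out <- data.frame(feature_id = character(0),
                          regulation_direction = character(0),
                          min_p = numeric(0),
                          classification = character(0),
                          stringsAsFactors = FALSE)
        return(out)
    }
    phenos <- unique(corr$phenotype)
    rows <- lapply(feats, function(f) {
        sub <- corr[corr$feature_id == f, ]
        sub <- sub[match(phenos, sub$phenotype), ]
        dirA <- concord$direction_A[match(f, concord$feature_id)]
        depleted <- if (factorRemoved) dirA > 0 else dirA < 0
        regDir <- if (depleted) "depleted_by_factor" else "enriched_by_factor"
        rho <- sub$rho; p <- sub$p
        ok <- sub$testable & !is.na(rho) & !is.na(p)
        sigNeg <- ok & rho < 0 & p < alpha
        sigPos <- ok & rho > 0 & p < alpha
        pass <- function(v) if (requireAll) all(v) else any(v)
        mixed <- any(ok & rho < 0) && any(ok & rho > 0)
        cls <- "not_candidate"
        if (!mixed && all(ok)) {
            if (depleted && pass(sigNeg) && all(rho < 0))
                cls <- "candidate_improver"
            else if (!depleted && pass(sigPos) && all(rho > 0))
                cls <- "candidate_worsener"
        }
        row <- data.frame(feature_id = f, regulation_direction = regDir,
                          stringsAsFactors = FALSE)
        for (j in seq_along(phenos)) {
            row[[paste0("rho_", phenos[j])]] <- rho[j]
            row[[paste0("p_", phenos[j])]] <- p[j]
        }
        row$min_p <- if (any(ok)) min(p[ok]) else NA_real_
        row$classification <- cls
        row
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$min_p, out$feature_id, na.last = TRUE), ]
    rownames(out) <- NULL
    out
}

#' Summarize sign consistency of per-group correlations
#'
#' Given each gene's correlation with the target microbe in every subject
#' group, counts genes whose correlations share the same (nonzero) sign in
#' all groups and tests, with the exact one-proportion test against 0.5,
#' whether the split of consistent genes between negative and positive is
#' compatible with chance.
#'
#' @param r matrix of correlation coefficients, genes in rows and groups in
#'   columns (no missing values).
#' @return list with `n_genes_tested`, `n_consistent`,
#'   `n_consistent_negative`, `n_consistent_positive` and
#'   `proportion_test_p` (two-sided; `NA` when no gene is consistent).
#' @export
signConsistencySummary <- function(r) {
    r <- as.matrix(r)
    if (anyNA(r))
        stop("correlation matrix must not contain missing values",
             call. = FALSE)
    allNeg <- rowSums(r < 0) == ncol(r)
    allPos <- rowSums(r > 0) == ncol(r)
    nNeg <- sum(allNeg); nPos <- sum(allPos)
    nCons <- nNeg + nPos
    p <- if (nCons > 0)
        oneProportionTest(nNeg, nCons, 0.5, "two_sided")$p_value
    else NA_real_
    list(n_genes_tested = nrow(r),
         n_consistent = nCons,
         n_consistent_negative = nNeg,
         n_consistent_positive = nPos,
         proportion_test_p = p)
}
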