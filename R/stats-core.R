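#' @importFrom stats t.test p.adjust cor.test binom.test pchisq pt cor
#'   complete.cases setNames var sd dbinom
NULL

.checkNumericVector <- function(x, name) {
    if (!is.numeric(x) || any(!is.finite(x)))
        stop(sprintf("'%s' must be a finite numeric vector", name),
             call. = FALSE)
}

#' Two-group location test
#'
#' Welch (unequal variance, the default) or pooled-variance two-sample t-test
#' with a two-sided p value. This is the per-feature test used by
#' [differentialFeatures()].
#'
#' @param x,y numeric vectors of length >= 2.
#' @param varEqual logical; `FALSE` (default) for the Welch statistic with
#'   Welch-Satterthwaite degrees of freedom, `TRUE` for the pooled-variance
#'   statistic.
#' @param feature optional feature label used in error messages.
#' @return list with `statistic` (t), `p_value` (two-sided) and `df`.
#' @examples
#' twoGroupTest(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
twoGroupTest <- function(x, y, varEqual = FALSE, feature = NULL) {
    .checkNumericVector(x, "x"); .checkNumericVector(y, "y")
    if (length(x) < 2L || length(y) < 2L)
        stop("both samples must contain at least 2 observations",
             call. = FALSE)
    if (var(x) == 0 && var(y) == 0) {
        lab <- if (is.null(feature)) "input" else sprintf("feature '%s'",
                                                          feature)
        stop(sprintf("degenerate %s: both samples are constant", lab),
             call. = FALSE)
    }
    ht <- t.test(x, y, var.equal = varEqual)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter))
}

# Row-wise Welch t on two sample matrices (features in rows). Used by the
# differential-abundance stage so that replicate-heavy simulations stay fast;
# unit tests pin it to stats::t.test. Rows where both groups are constant get
# NA statistics (flagged degenerate upstream).
.rowWelch <- function(a, b) {
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1L)
    vb <- rowSums((b - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    degen <- va == 0 & vb == 0
    tstat[degen] <- NA_real_; p[degen] <- NA_real_; df[degen] <- NA_real_
    list(statistic = tstat, p_value = p, df = df, degenerate = degen,
         mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. `NA`
#' entries are passed through unadjusted and do not count toward the number
#' of tests.
#'
#' @param p numeric vector of p values in `[0, 1]` (`NA` allowed).
#' @return numeric vector of q values, same length and order as `p`.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (!is.numeric(p))
        stop("'p' must be numeric", call. = FALSE)
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p values must lie in [0, 1]", call. = FALSE)
    p.adjust(p, method = "BH")
}

#' Fisher's combined probability test
#'
#' Combines k independent p values into the statistic
#' \eqn{\chi^2 = -2 \sum_i \log P_i}, referred to the upper tail of a
#' chi-squared distribution with 2k degrees of freedom. Used to merge the
#' per-group correlation p values when reconstructing the gene network.
#'
#' @param p numeric vector of k >= 1 p values in `(0, 1]`. Exact zeros are
#'   clamped to `floor` (with a warning) so the log stays finite.
#' @param floor lower clamp applied to zero p values.
#' @return list with `chi2`, `k`, `df` (= 2k) and `p_combined`.
#' @examples
#' fisherCombined(rep(0.05, 4))
#' @export
fisherCombined <- function(p, floor = 1e-300) {
    .checkNumericVector(p, "p")
    if (length(p) < 1L)
        stop("at least one p value is required", call. = FALSE)
    if (any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]", call. = FALSE)
    if (any(p == 0)) {
        warning(sprintf("p value(s) of 0 clamped to %g", floor))
        p <- pmax(p, floor)
    }
    k <- length(p)
    chi2 <- -2 * sum(log(p))
    list(chi2 = chi2, k = k, df = 2L * k,
         p_combined = pchisq(chi2, df = 2 * k, lower.tail = FALSE))
}

# Vectorised combined p for a matrix of per-group p values (rows = items,
# cols = groups); zeros clamped silently at the same default floor.
.fisherCombinedRows <- function(pmat, floor = 1e-300) {
    pmat <- pmax(pmat, floor)
    chi2 <- -2 * rowSums(log(pmat))
    k <- ncol(pmat)
    list(chi2 = chi2,
         p_combined = pchisq(chi2, df = 2 * k, lower.tail = FALSE))
}

.corrTest <- function(x, y, method, xname = "x", yname = "y") {
    .checkNumericVector(x, xname); .checkNumericVector(y, yname)
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length", call. = FALSE)
    if (length(x) < 3L)
        stop("at least 3 paired observations are required", call. = FALSE)
    if (sd(x) == 0 || sd(y) == 0)
        stop("degenerate input: constant vector has no defined correlation",
             call. = FALSE)
    ht <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    list(statistic = unname(ht$estimate), p_value = ht$p.value,
         df = length(x) - 2)
}

#' Pearson product-moment correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `statistic` (r), `p_value` (two-sided, from the t
#'   transform of r) and `df` (n - 2).
#' @examples
#' pearsonCorr(1:5, c(2, 1, 4, 3, 6))
#' @export
pearsonCorr <- function(x, y) .corrTest(x, y, "pearson")

#' Spearman rank correlation with two-sided p value
#'
#' Pearson correlation of tie-averaged ranks; p from the t transform (the
#' large-sample approximation, appropriate for the cohort-scale screens this
#' package performs).
#'
#' @inheritParams pearsonCorr
#' @return list with `statistic` (rho), `p_value` and `df`.
#' @export
spearmanCorr <- function(x, y) .corrTest(x, y, "spearman")

# Correlation p value from the t transform of r, vectorised.
.corrPvalue <- function(r, n) {
    r <- pmin(pmax(r, -1), 1)
    df <- n - 2
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    p[abs(r) == 1] <- 0
    p
}

#' Exact one-proportion (binomial) test
#'
#' Exact binomial tail probability that `successes` out of `n` is compatible
#' with success probability `p0`. The two-sided p value sums the
#' probabilities of all outcomes no more likely than the observed count
#' (minimum-likelihood rule).
#'
#' @param successes,n non-negative integers, `successes <= n`, `n >= 1`.
#' @param p0 null success probability.
#' @param alternative one of `"two_sided"`, `"greater"`, `"less"`.
#' @return list with `statistic` (observed proportion) and `p_value`.
#' @examples
#' oneProportionTest(69, 69, 0.5, "greater")
#' @export
oneProportionTest <- function(successes, n, p0 = 0.5,
                              alternative = c("two_sided", "greater",
                                              "less")) {
    alternative <- match.arg(alternative)
    if (!is.numeric(successes) || !is.numeric(n) ||
        successes != round(successes) || n != round(n))
        stop("'successes' and 'n' must be integers", call. = FALSE)
    if (n < 1L || successes < 0L || successes > n)
        stop("need 0 <= successes <= n and n >= 1", call. = FALSE)
    if (p0 <= 0 || p0 >= 1)
        stop("'p0' must lie strictly within (0, 1)", call. = FALSE)
    alt <- c(two_sided = "two.sided", greater = "greater",
             less = "less")[[alternative]]
    ht <- binom.test(successes, n, p = p0, alternative = alt)
    list(statistic = successes / n, p_value = ht$p.value)
}

#' Ascending ranks with average ties
#'
#' Smallest value receives rank 1; tied values share the average of the ranks
#' they cover, so ranks always sum to n(n+1)/2. This is the rank convention
#' of the four-source regulator score.
#'
#' @param values numeric vector without missing values.
#' @return numeric vector of ranks (empty input gives an empty vector).
#' @examples
#' rankAscending(c(3, 1, 3))
#' @export
rankAscending <- function(values) {
    if (length(values) == 0L) return(numeric(0))
    if (!is.numeric(values) || anyNA(values))
        stop("'values' must be numeric with no missing entries",
             call. = FALSE)
    rank(values, ties.method = "average")
}
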