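# Shared fixture builders; everything is generated in code at test time.

makeCountsTable <- function(nFeat = 4, nSamp = 3, seed = 1) {
    set.seed(seed)
    m <- matrix(rpois(nFeat * nSamp, 50), nFeat, nSamp,
                dimnames = list(sprintf("f%02d", seq_len(nFeat)),
                                sprintf("s%02d", seq_len(nSamp))))
    FeatureTable(m, kind = "counts")
}

# Two-group relative-abundance table with optionally one planted feature
# shifted by `fold` in the first `nPer` samples.
makeShiftedTable <- function(nFeat = 30, nPer = 10, fold = 1, cv = 0.2,
                             seed = 1) {
    set.seed(seed)
    base <- runif(nFeat, 0.5, 2)
    base[1] <- 0.15     # planted feature is minor, so a fold change on it
                        # barely perturbs the rest of the composition
    m <- sapply(seq_len(2 * nPer), function(j) {
        mult <- if (j <= nPer) c(fold, rep(1, nFeat - 1)) else rep(1, nFeat)
        v <- base * mult * exp(rnorm(nFeat, 0, cv))
        v / sum(v)
    })
    dimnames(m) <- list(sprintf("f%02d", seq_len(nFeat)),
                        sprintf("s%02d", seq_len(2 * nPer)))
    list(table = FeatureTable(m, kind = "relative"),
         meta = data.frame(
             sample_id = colnames(m),
             group = rep(c("perturbed", "control"), each = nPer),
             experiment = "X", stringsAsFactors = FALSE))
}

# k expression groups where genes in `modules` load on a latent factor.
makeExprGroups <- function(genes, modules = list(), loading = 0.9,
                           nPerGroup = c(8, 7, 9, 10), seed = 1) {
    set.seed(seed)
    lapply(setNames(seq_along(nPerGroup),
                    paste0("grp", seq_along(nPerGroup))), function(g) {
        n <- nPerGroup[g]
        x <- matrix(rnorm(length(genes) * n), length(genes), n,
                    dimnames = list(genes,
                                    sprintf("grp%d_s%02d", g, seq_len(n))))
        for (mod in modules) {
            f <- rnorm(n)
            x[mod, ] <- loading * rep(f, each = length(mod)) +
                sqrt(1 - loading^2) * x[mod, , drop = FALSE]
        }
        x
    })
}

# Independent Floyd-Warshall all-pairs shortest paths (hop counts).
floydWarshall <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    d[adj > 0] <- 1
    for (k in seq_len(n))
        for (i in seq_len(n)) {
            nd <- d[i, k] + d[k, ]
            upd <- nd < d[i, ]
            d[i, upd] <- nd[upd]
        }
    d
}

# Independent brute-force four-source rank-sum (loop-based average ties).
bruteForceRanks <- function(sources) {
    rankAvg <- function(v) {
        sapply(seq_along(v), function(i)
            sum(v < v[i]) + (1 + sum(v == v[i])) / 2)
    }
    tot <- rankAvg(sources$s1_abs_avg_corr) +
        rankAvg(sources$s2_avg_shortest_path) +
        rankAvg(sources$s3_abs_log10_fc) +
        rankAvg(sources$s4_signed_abs_avg_corr)
    ord <- order(-tot, sources$gene_id)
    data.frame(gene_id = sources$gene_id[ord], total_score = tot[ord],
               final_rank = seq_along(tot), stringsAsFactors = FALSE)
}
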