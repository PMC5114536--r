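test_that("per-group correlations combine per the Fisher construction", {
    genes <- sprintf("g%02d", 1:6)
    eg <- makeExprGroups(genes, seed = 31)
    # duplicate gene with tiny jitter: near-perfect correlation everywhere
    for (g in names(eg))
        eg[[g]]["g02", ] <- eg[[g]]["g01", ] +
            rnorm(ncol(eg[[g]]), 0, 0.01)
    pc <- perGroupCorrelations(eg)
    pair <- pc[pc$gene_a == "g01" & pc$gene_b == "g02", ]
    rcols <- startsWith(names(pair), "r_")
    expect_true(all(as.numeric(pair[rcols]) > 0.99))
    expect_lt(pair$p_combined, 1e-10)
    # combined statistic equals -2 * sum(log p) for every pair
    pcols <- paste0("p_", substring(names(pc)[rcols], 3))
    expect_equal(pc$chi2, -2 * rowSums(log(as.matrix(pc[pcols]))),
                 tolerance = 1e-10)
    # per-group values match cor.test
    ct <- cor.test(eg$grp1["g03", ], eg$grp1["g04", ])
    expect_equal(pc$r_grp1[pc$gene_a == "g03" & pc$gene_b == "g04"],
                 unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pc$p_grp1[pc$gene_a == "g03" & pc$gene_b == "g04"],
                 ct$p.value, tolerance = 1e-12)
})

test_that("a single group reduces the combined p to the per-group p", {
    genes <- c("a", "b", "c")
    eg <- makeExprGroups(genes, nPerGroup = 10, seed = 5)
    pc <- perGroupCorrelations(eg)
    expect_equal(pc$p_combined, pc$p_grp1, tolerance = 1e-10)
})

test_that("constant genes make pairs untestable rather than erroring", {
    genes <- c("a", "b", "c")
    eg <- makeExprGroups(genes, seed = 6)
    eg$grp2["b", ] <- 5
    pc <- perGroupCorrelations(eg)
    expect_false(any(pc$testable[pc$gene_a == "b" | pc$gene_b == "b"]))
    expect_true(all(pc$testable[pc$gene_a == "a" & pc$gene_b == "c"]))
})

test_that("null correlation p values are roughly uniform", {
    genes <- sprintf("g%03d", 1:60)
    eg <- makeExprGroups(genes, nPerGroup = c(8, 8, 8, 8), seed = 41)
    pc <- perGroupCorrelations(eg)
    frac <- mean(pc$p_combined < 0.01)
    expect_lt(frac, 0.03)
    expect_gt(mean(pc$p_combined < 0.5), 0.4)
})

test_that("edge admissibility enforces all four criteria", {
    r <- c(0.8, 0.7, 0.9, 0.6)
    p <- c(0.01, 0.05, 0.005, 0.1)
    pComb <- fisherCombined(p)$p_combined
    # positive correlations, both genes down-regulated: admissible
    expect_true(edgeAdmissible(r, p, pComb, -1.2, -0.8))
    # positive correlations but opposite fold changes: sign rule fails
    expect_false(edgeAdmissible(r, p, pComb, -1.2, 0.8))
    # one within-group p above threshold kills the edge
    expect_false(edgeAdmissible(r, c(0.01, 0.5, 0.005, 0.1),
                                pComb, -1.2, -0.8))
    # inconsistent correlation signs kill the edge
    expect_false(edgeAdmissible(c(0.8, 0.7, -0.9, 0.6), p, pComb,
                                -1.2, -0.8))
    # combined p above threshold kills the edge
    expect_false(edgeAdmissible(r, p, 0.02, -1.2, -0.8))
    # zero fold change cannot satisfy the sign rule
    expect_false(edgeAdmissible(r, p, pComb, 0, -0.8))
})

test_that("network reconstruction separates planted modules from noise", {
    genes <- sprintf("g%02d", 1:30)
    modA <- genes[1:10]; modB <- genes[11:20]
    eg <- makeExprGroups(genes, modules = list(modA, modB), loading = 0.9,
                         nPerGroup = c(14, 14, 14, 14), seed = 51)
    fc <- setNames(c(rep(-1, 20), rnorm(10, 0, 0.3)), genes)
    net <- buildNetwork(eg, fc)
    ed <- networkEdges(net)
    within <- function(mod)
        sum(ed$gene_a %in% mod & ed$gene_b %in% mod)
    expect_gte(within(modA), 0.9 * choose(10, 2))
    expect_gte(within(modB), 0.9 * choose(10, 2))
    cross <- sum(ed$gene_a %in% modA & ed$gene_b %in% modB)
    expect_lte(cross, 0.01 * 100)
    # noise genes stay out of the network
    noise <- genes[21:30]
    expect_lte(sum(networkNodes(net)$gene %in% noise), 1)
    expect_lte(membershipFraction(net), 22 / 30)

    # every reported edge re-passes the admissibility rule (self-audit)
    rcols <- names(ed)[startsWith(names(ed), "r_")]
    pcols <- paste0("p_", substring(rcols, 3))
    for (i in seq_len(nrow(ed)))
        expect_true(edgeAdmissible(
            as.numeric(ed[i, rcols]), as.numeric(ed[i, pcols]),
            ed$p_combined[i], fc[ed$gene_a[i]], fc[ed$gene_b[i]]))
})

test_that("network construction is invariant to gene and group order", {
    genes <- sprintf("g%02d", 1:12)
    eg <- makeExprGroups(genes, modules = list(genes[1:6]), loading = 0.85,
                         seed = 61)
    fc <- setNames(rep(-1, 12), genes)
    net1 <- buildNetwork(eg, fc)
    set.seed(1)
    shuf <- lapply(rev(eg), function(m) m[sample(nrow(m)), ])
    net2 <- buildNetwork(shuf, fc)
    canon <- function(net) {
        ed <- networkEdges(net)
        sort(paste(ed$gene_a, ed$gene_b))
    }
    expect_identical(canon(net1), canon(net2))
    expect_identical(sort(networkNodes(net1)$gene),
                     sort(networkNodes(net2)$gene))
})

test_that("a single coupled pair yields a two-node network", {
    genes <- c("a", "b", "c")
    eg <- makeExprGroups(genes, seed = 7)
    for (g in names(eg))
        eg[[g]]["b", ] <- eg[[g]]["a", ] + rnorm(ncol(eg[[g]]), 0, 0.1)
    fc <- c(a = -1, b = -1, c = 0.5)
    net <- buildNetwork(eg, fc)
    expect_equal(nrow(networkNodes(net)), 2)
    expect_equal(nrow(networkEdges(net)), 1)
    expect_equal(networkEdges(net)$sign, 1L)
    expect_error(buildNetwork(eg, fc, geneSubset = "a"), "at least 2")
    expect_error(buildNetwork(eg, fc[1:2]), "fold change missing")
})

test_that("average shortest path lengths match known graphs", {
    star <- igraph::make_star(6, mode = "undirected")
    igraph::V(star)$name <- paste0("v", 1:6)
    mkNet <- function(g) {
        nodes <- data.frame(gene = igraph::V(g)$name, log2_fc = -1,
                            degree = igraph::degree(g),
                            avg_shortest_path = NA_real_,
                            stringsAsFactors = FALSE)
        ed <- igraph::as_data_frame(g)
        edges <- data.frame(gene_a = ed$from, gene_b = ed$to,
                            stringsAsFactors = FALSE)
        new("GeneNetwork", graph = g, nodes = nodes, edges = edges,
            membershipFraction = 1, params = list())
    }
    net <- mkNet(star)
    expect_equal(avgShortestPathLength(net, "v1"), 1)          # hub
    expect_equal(avgShortestPathLength(net, "v2"), (1 + 4 * 2) / 5)
    path3 <- igraph::make_graph(~ a - b, b - c)
    expect_equal(avgShortestPathLength(mkNet(path3), "a"), 1.5)
    expect_error(avgShortestPathLength(net, "zz"), "not a network member")
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
    set.seed(71)
    for (rep in 1:30) {
        n <- sample(5:50, 1)
        pEdge <- sample(c(0.05, 0.2, 0.5), 1)
        adj <- matrix(0, n, n)
        adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, pEdge)
        adj <- adj + t(adj)
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        d <- igraph::distances(g, algorithm = "unweighted")
        fw <- floydWarshall(adj)
        expect_equal(unname(d), fw)
    }
})

test_that("per-node path length lies between 1 and the component diameter", {
    genes <- sprintf("g%02d", 1:15)
    eg <- makeExprGroups(genes, modules = list(genes[1:8]), loading = 0.8,
                         seed = 81)
    fc <- setNames(rep(-1, 15), genes)
    net <- buildNetwork(eg, fc)
    nd <- networkNodes(net)
    if (nrow(nd) > 1) {
        diam <- igraph::diameter(networkGraph(net))
        expect_true(all(nd$avg_shortest_path >= 1))
        expect_true(all(nd$avg_shortest_path <= diam))
    }
})
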