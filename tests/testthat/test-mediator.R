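test_that("abundance filter selects exactly the planted samples", {
    set.seed(17)
    n <- 100
    above <- sample(n, 40)
    m <- matrix(0.001, 2, n,
                dimnames = list(c("akk", "other"), sprintf("s%03d", 1:n)))
    m["akk", above] <- runif(40, 0.011, 0.3)
    m["other", ] <- 1 - m["akk", ]
    ft <- FeatureTable(m, "relative")
    expect_setequal(selectSamplesByFeature(ft, "akk", 0.01),
                    sprintf("s%03d", sort(above)))
    expect_equal(length(selectSamplesByFeature(ft, "akk", 0)), n)
    expect_error(selectSamplesByFeature(ft, "missing"), "unknown feature")
})

test_that("phenotype correlations recover a planted mediator relation", {
    set.seed(23)
    n <- 50
    ab <- runif(n, 0, 0.2)
    other <- (1 - ab) / 2
    m <- rbind(akk = ab, o1 = other, o2 = other)
    colnames(m) <- sprintf("s%02d", 1:n)
    meta <- data.frame(sample_id = colnames(m),
                       glucose = 100 - 50 * ab + rnorm(n, 0, 5),
                       stringsAsFactors = FALSE)
    ft <- FeatureTable(m, "relative")
    res <- phenotypeCorrelations(ft, meta, features = "akk",
                                 phenotypes = "glucose")
    expect_lt(res$rho, 0)
    expect_lt(res$p, 0.01)
    expect_equal(res$n, n)

    # a feature identical to the phenotype correlates perfectly
    meta$copy <- m["o1", ]
    res <- phenotypeCorrelations(ft, meta, features = "o1",
                                 phenotypes = "copy")
    expect_equal(res$rho, 1)

    # pairwise-complete handling and untestable flags
    meta$sparse <- NA_real_
    meta$sparse[1:2] <- c(1, 2)
    res <- phenotypeCorrelations(ft, meta, features = "akk",
                                 phenotypes = "sparse")
    expect_false(res$testable)
    expect_equal(res$n, 2)
    expect_true(is.na(res$rho))
    meta$partial <- meta$glucose
    meta$partial[1:10] <- NA
    res <- phenotypeCorrelations(ft, meta, features = "akk",
                                 phenotypes = "partial")
    expect_equal(res$n, 40)
})

test_that("mediator nomination applies the direction-matching sign rule", {
    concord <- data.frame(
        feature_id = c("up_neg", "up_pos", "dn_pos", "dn_neg", "mixed",
                       "weak"),
        direction_A = c(1, 1, -1, -1, 1, 1),
        direction_B = c(1, 1, -1, -1, 1, 1),
        q_A = 0.01, q_B = 0.01, concordant = TRUE,
        stringsAsFactors = FALSE)
    corr <- rbind(
        data.frame(feature_id = concord$feature_id, phenotype = "glu",
                   rho = c(-0.8, 0.8, 0.8, -0.8, -0.6, -0.2),
                   p = c(0.001, 0.001, 0.001, 0.001, 0.01, 0.4),
                   n = 20, testable = TRUE),
        data.frame(feature_id = concord$feature_id, phenotype = "auc",
                   rho = c(-0.7, 0.7, 0.7, -0.7, 0.5, -0.3),
                   p = c(0.002, 0.002, 0.002, 0.002, 0.02, 0.3),
                   n = 20, testable = TRUE))
    res <- nominateMediators(concord, corr)
    cls <- setNames(res$classification, res$feature_id)
    # factor removed in perturbed group: up == depleted by the factor
    expect_equal(cls[["up_neg"]], "candidate_improver")
    expect_equal(cls[["dn_pos"]], "candidate_worsener")
    expect_equal(cls[["up_pos"]], "not_candidate")
    expect_equal(cls[["dn_neg"]], "not_candidate")
    expect_equal(cls[["mixed"]], "not_candidate")  # mixed signs never qualify
    expect_equal(cls[["weak"]], "not_candidate")   # below alpha
    # ordering by min p with feature-id tiebreak (the four 0.001 records tie)
    expect_equal(res$feature_id[1:4],
                 c("dn_neg", "dn_pos", "up_neg", "up_pos"))
    expect_equal(res$feature_id[5:6], c("mixed", "weak"))

    # opposite perturbation polarity flips the mapping
    res2 <- nominateMediators(concord, corr, factorRemoved = FALSE)
    cls2 <- setNames(res2$classification, res2$feature_id)
    expect_equal(cls2[["dn_neg"]], "candidate_improver")
    expect_equal(cls2[["up_pos"]], "candidate_worsener")

    # any-of mode accepts a single significant phenotype if signs agree
    corr$p[corr$feature_id == "up_neg" & corr$phenotype == "auc"] <- 0.2
    res3 <- nominateMediators(concord, corr, requireAll = FALSE)
    expect_equal(res3$classification[res3$feature_id == "up_neg"],
                 "candidate_improver")
    res4 <- nominateMediators(concord, corr)
    expect_equal(res4$classification[res4$feature_id == "up_neg"],
                 "not_candidate")
})

test_that("nomination refuses correlations contaminated by controls", {
    concord <- data.frame(feature_id = "a", direction_A = 1,
                          direction_B = 1, q_A = 0.01, q_B = 0.01,
                          concordant = TRUE, stringsAsFactors = FALSE)
    corr <- data.frame(feature_id = "a", phenotype = "glu", rho = -0.5,
                       p = 0.01, n = 10, testable = TRUE)
    bad <- data.frame(sample_id = c("s1", "s2"),
                      group = c("perturbed", "control"))
    expect_error(nominateMediators(concord, corr, meta = bad,
                                   controlLabel = "control"),
                 "control-group label")
    ok <- data.frame(sample_id = c("s1", "s2"), group = "perturbed")
    expect_silent(res <- nominateMediators(concord, corr, meta = ok,
                                           controlLabel = "control"))
    expect_equal(res$classification, "candidate_improver")

    # correlated features missing from the concordance set warn
    orphan <- rbind(corr, data.frame(feature_id = "ghost",
                                     phenotype = "glu", rho = 0.1, p = 0.5,
                                     n = 10, testable = TRUE))
    expect_warning(nominateMediators(concord, orphan), "ghost")
})

test_that("sign-consistency summary counts and tests shared signs", {
    s <- signConsistencySummary(matrix(c(-0.2, -0.3, -0.1), 1))
    expect_equal(s$n_consistent, 1)
    expect_equal(s$n_consistent_negative, 1)
    s <- signConsistencySummary(matrix(c(-0.2, 0.3, -0.1), 1))
    expect_equal(s$n_consistent, 0)
    expect_true(is.na(s$proportion_test_p))

    r <- rbind(matrix(-runif(69 * 3), 69),
               matrix(rnorm(30 * 3), 30))
    s <- signConsistencySummary(r)
    expect_equal(s$n_genes_tested, 99)
    expect_equal(s$n_consistent_negative, 69 +
                 sum(rowSums(r[70:99, ] < 0) == 3))
    expect_equal(s$n_consistent,
                 s$n_consistent_negative + s$n_consistent_positive)
    expect_error(signConsistencySummary(matrix(c(NA, 1), 1)), "missing")
})
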