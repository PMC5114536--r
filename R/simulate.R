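#' @importFrom stats rnorm runif rgamma rmultinom rexp
NULL

# Deterministic per-component seed derived from the master seed, so each
# logical component (taxa, phenotype, expression) has its own stream and
# adding a component never perturbs the draws of another. Kept < 2^31.
.componentSeed <- function(seed, component) {
    h <- sum(utf8ToInt(component) * seq_len(nchar(component)))
    as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles all generator parameters with their defaults. The defaults
#' emulate a paired perturbation design: two independent two-group
#' microbiome experiments of 10 samples per group over 200 taxa, half of
#' which respond to the perturbation (a small bloom set, including the
#' mediator, increases five-fold; the rest are depleted by a fold solved so
#' total composition weight is conserved); one planted mediator taxon
#' driving the phenotype; and four groups of expression
#' samples (8, 7, 9 and 10 samples, as in typical multi-strain panels)
#' carrying planted correlation modules and one planted regulator gene
#' negatively coupled to the microbe.
#'
#' @param seed master seed (mandatory; every stream derives from it).
#' @param nTaxa number of taxa.
#' @param nSamplesPerGroup microbiome samples per group and experiment.
#' @param nRegulatedTaxa taxa responding to the perturbation (includes the
#'   mediator).
#' @param regulationFold fold change applied to blooming regulated taxa in
#'   the perturbed group (> 1); depleted taxa get the complementary fold
#'   that keeps total composition weight at one (recorded in the truth).
#' @param mediatorEffect phenotype units per unit relative abundance of the
#'   mediator (beta1; negative = improver).
#' @param phenotypeNoise residual phenotype s.d. (sigma).
#' @param phenotypeBaseline intercept of the fasting-glucose model (beta0,
#'   mg/dl).
#' @param aucBaseline,aucScale intercept and scale of the second phenotype
#'   (AUC-GTT, arbitrary units): `aucBaseline + aucScale * beta1 * abundance`
#'   plus independent noise of s.d. `aucScale * phenotypeNoise`, so both
#'   metrics respond to the mediator but carry their own measurement error.
#' @param dirichletPrecision precision of the Dirichlet-multinomial taxa
#'   model (larger = less overdispersion; the default gives a c. 50%
#'   compositional CV for a taxon at 0.5% abundance).
#' @param librarySize sequencing reads per sample.
#' @param mediatorBaselineWeight baseline relative abundance of the mediator
#'   taxon (an abundant mucin-specialist-like taxon).
#' @param mediatorSpread extra between-sample biological variability of the
#'   mediator (s.d. of a log-normal factor on its Dirichlet weight).
#' @param nGenes number of signature genes.
#' @param nGroups number of expression sample groups.
#' @param nSamplesPerExprGroup samples per expression group (scalar or
#'   vector of length `nGroups`).
#' @param moduleSizes sizes of the planted co-expression modules.
#' @param loadingRange range of per-gene loadings on the module latent
#'   factor.
#' @param regulatorCoupling target Pearson correlation between the planted
#'   regulator gene and the microbe (in (-1, 0) for an inhibitor).
#' @param regulatorLog2Fc log2 fold change assigned to the regulator
#'   (large magnitude, matching a strongly cytokine-dependent gene).
#' @return list of validated parameters (class `SimulationConfig`).
#' @export
simulationConfig <- function(seed,
                             nTaxa = 200L,
                             nSamplesPerGroup = 10L,
                             nRegulatedTaxa = 100L,
                             regulationFold = 5,
                             mediatorEffect = -50,
                             phenotypeNoise = 5,
                             phenotypeBaseline = 150,
                             aucBaseline = 300,
                             aucScale = 3,
                             dirichletPrecision = 800,
                             librarySize = 50000L,
                             mediatorBaselineWeight = 0.06,
                             mediatorSpread = 0.7,
                             nGenes = 200L,
                             nGroups = 4L,
                             nSamplesPerExprGroup = c(8L, 7L, 9L, 10L),
                             moduleSizes = c(30L, 25L, 20L),
                             loadingRange = c(0.8, 0.97),
                             regulatorCoupling = -0.85,
                             regulatorLog2Fc = -2.5) {
    if (missing(seed))
        stop("'seed' is mandatory: the generator has no implicit entropy",
             call. = FALSE)
    cfg <- list(seed = as.integer(seed), nTaxa = as.integer(nTaxa),
                nSamplesPerGroup = as.integer(nSamplesPerGroup),
                nRegulatedTaxa = as.integer(nRegulatedTaxa),
                regulationFold = regulationFold,
                mediatorEffect = mediatorEffect,
                phenotypeNoise = phenotypeNoise,
                phenotypeBaseline = phenotypeBaseline,
                aucBaseline = aucBaseline, aucScale = aucScale,
                dirichletPrecision = dirichletPrecision,
                librarySize = as.integer(librarySize),
                mediatorBaselineWeight = mediatorBaselineWeight,
                mediatorSpread = mediatorSpread,
                nGenes = as.integer(nGenes), nGroups = as.integer(nGroups),
                nSamplesPerExprGroup =
                    as.integer(rep_len(nSamplesPerExprGroup, nGroups)),
                moduleSizes = as.integer(moduleSizes),
                loadingRange = loadingRange,
                regulatorCoupling = regulatorCoupling,
                regulatorLog2Fc = regulatorLog2Fc)
    .validateSimulationConfig(cfg)
    class(cfg) <- "SimulationConfig"
    cfg
}

.validateSimulationConfig <- function(cfg) {
    errs <- character(0)
    pos <- c("nTaxa", "nSamplesPerGroup", "nRegulatedTaxa",
             "phenotypeNoise", "dirichletPrecision", "librarySize",
             "mediatorBaselineWeight", "mediatorSpread", "nGenes",
             "nGroups")
    for (nm in pos)
        if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0))
            errs <- c(errs, sprintf("'%s' must be positive", nm))
    if (cfg$regulationFold < 1)
        errs <- c(errs, "'regulationFold' must be >= 1")
    if (cfg$nRegulatedTaxa > cfg$nTaxa)
        errs <- c(errs, "'nRegulatedTaxa' cannot exceed 'nTaxa'")
    if (cfg$mediatorBaselineWeight >= 1)
        errs <- c(errs, "'mediatorBaselineWeight' must be < 1")
    if (cfg$mediatorBaselineWeight * cfg$regulationFold >= 1)
        errs <- c(errs, paste("infeasible composition: regulationFold pushes",
                              "the mediator proportion above 1"))
    if (cfg$regulatorCoupling <= -1 || cfg$regulatorCoupling >= 0)
        errs <- c(errs, paste("'regulatorCoupling' must lie in (-1, 0)",
                              "for the inhibitor scenario"))
    if (sum(cfg$moduleSizes) + 5L > cfg$nGenes)
        errs <- c(errs, "'moduleSizes' leave no room for unstructured genes")
    if (any(cfg$nSamplesPerExprGroup < 3L))
        errs <- c(errs, "expression groups need >= 3 samples")
    if (length(errs))
        stop(paste(errs, collapse = "; "), call. = FALSE)
    invisible(TRUE)
}

# One Dirichlet-multinomial sample group: weights w (unnormalized), the
# mediator row gets an extra per-sample log-normal factor.
.sampleGroupCounts <- function(w, n, cfg, mediatorIdx, sampleIds) {
    alpha0 <- cfg$dirichletPrecision * (w / sum(w))
    counts <- matrix(0, length(w), n)
    for (j in seq_len(n)) {
        alpha <- alpha0
        alpha[mediatorIdx] <- alpha[mediatorIdx] *
            exp(rnorm(1, 0, cfg$mediatorSpread))
        g <- rgamma(length(alpha), shape = alpha, rate = 1)
        counts[, j] <- rmultinom(1, cfg$librarySize, g / sum(g))
    }
    colnames(counts) <- sampleIds
    counts
}

#' Simulate two paired microbiome perturbation experiments
#'
#' Draws two independent two-group experiments from a shared
#' Dirichlet-multinomial baseline. Regulated taxa have their baseline weight
#' multiplied by `regulationFold` (direction per taxon, recorded in the
#' truth) in the perturbed group of BOTH experiments. Phenotypes (fasting
#' glucose and AUC-GTT) are generated for perturbed-group samples only, as a
#' linear function of the planted mediator's realized relative abundance
#' plus noise. All randomness derives from `cfg$seed` via per-component
#' streams.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `tableA`, `tableB` (counts [FeatureTable-class]s),
#'   `meta` (per-sample metadata data.frame with `sample_id`, `group`,
#'   `experiment`, `fasting_glucose`, `auc_gtt`) and `truth` (regulated taxa
#'   with directions, the mediator id and the phenotype model parameters).
#' @export
simulateMicrobiomeExperiments <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(.componentSeed(cfg$seed, "taxa"))
    taxa <- sprintf("otu%03d", seq_len(cfg$nTaxa))
    w <- 0.8 + 0.8 * rexp(cfg$nTaxa)   # right-skewed, no rare tail
    mediatorIdx <- sample.int(cfg$nTaxa, 1L)
    # fix the mediator's baseline share of the composition
    w[mediatorIdx] <- 0
    w <- w / sum(w) * (1 - cfg$mediatorBaselineWeight)
    w[mediatorIdx] <- cfg$mediatorBaselineWeight
    regIdx <- c(mediatorIdx,
                sample(setdiff(seq_len(cfg$nTaxa), mediatorIdx),
                       cfg$nRegulatedTaxa - 1L))
    # The perturbation conserves total composition weight: a small set of
    # taxa (including the mediator) blooms by regulationFold while the
    # remaining regulated taxa are depleted by a fold solved exactly so the
    # perturbed weights still sum to one. Without this balance the
    # renormalization would imprint a spurious shared shift on every
    # unregulated taxon, which two experiments sharing the truth would then
    # reproducibly (and artifactually) call concordant.
    f <- cfg$regulationFold
    nUpTarget <- min(max(1L, round(0.05 * (cfg$nRegulatedTaxa - 1L))),
                     cfg$nRegulatedTaxa - 1L)
    foldDown <- NA_real_
    for (nUpOther in seq(nUpTarget, 0L)) {
        direction <- c(1, rep(1, nUpOther),
                       rep(-1, cfg$nRegulatedTaxa - 1L - nUpOther))
        upW <- sum(w[regIdx[direction == 1]])
        downW <- sum(w[regIdx[direction == -1]])
        foldDown <- (sum(w[regIdx]) - f * upW) / downW
        if (is.finite(foldDown) && foldDown > 0 && foldDown <= 1 + 1e-9)
            break
    }
    if (!is.finite(foldDown) || foldDown <= 0 || foldDown > 1 + 1e-9 ||
        any(w[regIdx[direction == 1]] * f > 0.95))
        stop("infeasible composition: regulationFold cannot be balanced",
             call. = FALSE)
    wPert <- w
    wPert[regIdx] <- wPert[regIdx] *
        ifelse(direction == 1, f, foldDown)
    n <- cfg$nSamplesPerGroup
    mkIds <- function(exp, grp) sprintf("%s_%s_%02d", exp, grp, seq_len(n))
    tables <- list()
    meta <- list()
    for (e in c("A", "B")) {
        cp <- .sampleGroupCounts(wPert, n, cfg, mediatorIdx,
                                 mkIds(e, "pert"))
        cc <- .sampleGroupCounts(w, n, cfg, mediatorIdx, mkIds(e, "ctrl"))
        m <- cbind(cp, cc)
        rownames(m) <- taxa
        tables[[e]] <- FeatureTable(m, kind = "counts")
        meta[[e]] <- data.frame(
            sample_id = colnames(m),
            group = rep(c("perturbed", "control"), each = n),
            experiment = e, stringsAsFactors = FALSE)
    }
    meta <- rbind(meta$A, meta$B)
    # phenotypes: perturbed samples only, driven by realized mediator RA
    set.seed(.componentSeed(cfg$seed, "phenotype"))
    meta$fasting_glucose <- NA_real_
    meta$auc_gtt <- NA_real_
    for (e in c("A", "B")) {
        m <- abundances(tables[[e]])
        ra <- m[mediatorIdx, ] / colSums(m)
        pert <- mkIds(e, "pert")
        mu <- cfg$mediatorEffect * ra[pert]
        rows <- match(pert, meta$sample_id)
        meta$fasting_glucose[rows] <- cfg$phenotypeBaseline + mu +
            rnorm(n, 0, cfg$phenotypeNoise)
        meta$auc_gtt[rows] <- cfg$aucBaseline + cfg$aucScale * mu +
            rnorm(n, 0, cfg$aucScale * cfg$phenotypeNoise)
    }
    truth <- list(regulated_taxa = taxa[regIdx],
                  directions = stats::setNames(direction, taxa[regIdx]),
                  mediator_taxon = taxa[mediatorIdx],
                  fold_up = f, fold_down = foldDown,
                  beta0 = cfg$phenotypeBaseline,
                  beta1 = cfg$mediatorEffect,
                  sigma = cfg$phenotypeNoise)
    list(tableA = tables$A, tableB = tables$B, meta = meta, truth = truth)
}

#' Simulate multi-group expression data with a planted regulator
#'
#' For each sample group, module genes load on a shared latent factor
#' (log-scale), producing within-module correlations whose sign is
#' consistent across groups and consistent with the genes' assigned fold
#' changes. One planted regulator gene is coupled to the per-sample microbe
#' abundance with target Pearson correlation `regulatorCoupling` in every
#' group; four bridge genes (two module-member anchors and two strongly
#' coupled partners) tie the regulator into module 1's component so it is a
#' network member while staying at the periphery of the dense module core. The remaining genes are
#' independent noise.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `exprGroups` (named list of gene x sample log2
#'   expression matrices), `microbeByGroup` (per-sample microbe abundances),
#'   `foldChanges` (named log2 fold-change vector) and `truth` (module
#'   memberships, regulator and bridge gene ids, coupling sign).
#' @export
simulateExpressionGroups <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(.componentSeed(cfg$seed, "expression"))
    genes <- sprintf("g%03d", seq_len(cfg$nGenes))
    nMod <- length(cfg$moduleSizes)
    special <- sample.int(cfg$nGenes, sum(cfg$moduleSizes) + 5L)
    moduleIdx <- split(special[seq_len(sum(cfg$moduleSizes))],
                       rep(seq_len(nMod), cfg$moduleSizes))
    regIdx <- special[sum(cfg$moduleSizes) + 1L]
    bridgeIdx <- special[sum(cfg$moduleSizes) + 2:5]
    loading <- stats::setNames(rep(NA_real_, cfg$nGenes), genes)
    for (m in moduleIdx)
        loading[m] <- runif(length(m), cfg$loadingRange[1L],
                            cfg$loadingRange[2L])
    # fold changes: module genes down-regulated (sign matches the positive
    # within-module correlations); noise genes random sign, small magnitude
    lfc <- stats::setNames(rnorm(cfg$nGenes, 0, 0.25), genes)
    for (m in moduleIdx)
        lfc[m] <- -exp(rnorm(length(m), 0, 0.3))
    lfc[regIdx] <- cfg$regulatorLog2Fc
    lfc[bridgeIdx] <- -exp(rnorm(4L, log(1.2), 0.2))
    rho <- cfg$regulatorCoupling            # negative: inhibitor scenario
    # regulator composition: dominated by the microbe coupling, with a
    # moderate loading on module 1's factor and a private component shared
    # with two bridge genes, so it reliably joins module 1's connected
    # component while staying at its periphery
    lR <- min(0.40, sqrt((1 - rho^2) * 0.55))
    cH <- min(0.33, sqrt((1 - rho^2) * 0.4))
    eReg <- sqrt(1 - rho^2 - lR^2 - cH^2)
    # bridge compositions (columns: private h, module factor, microbe):
    # the first anchors the regulator's neighbourhood to module 1, the
    # other two are strongly correlated partners of the regulator itself
    # two anchor bridges are bona fide module-1 members sharing part of the
    # regulator's signature; two partner bridges correlate strongly with the
    # regulator and with the anchors, completing a reliable chain
    # regulator - partner - anchor - module while keeping the regulator
    # itself outside the dense module core
    bcoef <- rbind(c(0.37, 0.85, 0.37),
                   c(0.37, 0.85, 0.37),
                   c(0.50, 0.55, 0.64),
                   c(0.50, 0.55, 0.64))
    eBridge <- sqrt(1 - rowSums(bcoef^2))
    exprGroups <- list()
    microbeByGroup <- list()
    for (gi in seq_len(cfg$nGroups)) {
        gname <- sprintf("grp%d", gi)
        n <- cfg$nSamplesPerExprGroup[gi]
        zMicro <- rnorm(n)
        microbe <- pmax(0.15 + 0.05 * zMicro, 0.001)
        x <- matrix(rnorm(cfg$nGenes * n), cfg$nGenes, n,
                    dimnames = list(genes, sprintf("%s_s%02d", gname,
                                                   seq_len(n))))
        fmod <- replicate(nMod, rnorm(n), simplify = FALSE)
        for (mi in seq_len(nMod)) {
            m <- moduleIdx[[mi]]
            l <- loading[m]
            x[m, ] <- l %o% fmod[[mi]] + sqrt(1 - l^2) * x[m, , drop = FALSE]
        }
        h <- rnorm(n)                       # regulator's latent component
        x[regIdx, ] <- rho * zMicro + lR * fmod[[1L]] + cH * h +
            eReg * x[regIdx, ]
        for (bi in seq_along(bridgeIdx)) {
            b <- bridgeIdx[bi]
            x[b, ] <- bcoef[bi, 1L] * h + bcoef[bi, 2L] * fmod[[1L]] -
                bcoef[bi, 3L] * zMicro + eBridge[bi] * x[b, ]
        }
        # shift to a plausible log2-expression scale
        x <- x * 1.2 + 8
        exprGroups[[gname]] <- x
        microbeByGroup[[gname]] <- stats::setNames(microbe, colnames(x))
    }
    truth <- list(modules = lapply(moduleIdx, function(i) genes[i]),
                  regulator_gene = genes[regIdx],
                  bridge_genes = genes[bridgeIdx],
                  coupling_sign = sign(rho),
                  rho_target = rho)
    list(exprGroups = exprGroups, microbeByGroup = microbeByGroup,
         foldChanges = lfc, truth = truth)
}
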