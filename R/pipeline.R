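#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

.configStop <- function(...) {
    stop(errorCondition(paste0(...), class = c("configError", "error")))
}

.pipelineDefaults <- function() {
    list(seed = 1L,
         fdr_tau = 0.1,
         alpha = 0.05,
         p_ind = 0.3,
         p_comb = 0.01,
         min_abund = 0.01,
         correlation_method = "spearman",
         simulation = list())
}

#' Validate a pipeline configuration
#'
#' Fills in the default thresholds (FDR tau 0.1, correlation alpha 0.05,
#' per-group edge p 0.3, combined edge p 0.01, abundance filter 0.01),
#' rejects unknown keys, and reports every type/range problem at once
#' rather than stopping at the first.
#'
#' @param config a named list, a path to a YAML file, or `NULL`/empty for
#'   all defaults.
#' @return the resolved configuration list.
#' @export
validateConfig <- function(config = NULL) {
    if (is.character(config)) {
        if (!file.exists(config))
            .configStop(sprintf("config file not found: %s", config))
        config <- read_yaml(config)
        if (is.null(config)) config <- list()
    }
    if (is.null(config)) config <- list()
    if (!is.list(config))
        .configStop("config must be a named list or YAML mapping")
    defaults <- .pipelineDefaults()
    unknown <- setdiff(names(config), names(defaults))
    errs <- character(0)
    if (length(unknown))
        errs <- c(errs, sprintf("unknown key(s): %s",
                                paste(unknown, collapse = ", ")))
    cfg <- utils::modifyList(defaults, config[setdiff(names(config),
                                                      unknown)])
    for (nm in c("fdr_tau", "alpha", "p_ind", "p_comb", "min_abund")) {
        v <- cfg[[nm]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v))
            errs <- c(errs, sprintf("'%s' must be a single number", nm))
        else if (nm != "min_abund" && (v <= 0 || v >= 1))
            errs <- c(errs, sprintf("'%s' must lie in (0, 1)", nm))
        else if (nm == "min_abund" && (v < 0 || v > 1))
            errs <- c(errs, sprintf("'%s' must lie in [0, 1]", nm))
    }
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
        is.na(cfg$seed) || cfg$seed != round(cfg$seed))
        errs <- c(errs, "'seed' must be a single integer")
    if (!is.character(cfg$correlation_method) ||
        !cfg$correlation_method %in% c("spearman", "pearson"))
        errs <- c(errs, "'correlation_method' must be spearman or pearson")
    if (!is.list(cfg$simulation))
        errs <- c(errs, "'simulation' must be a mapping of generator options")
    if (length(errs))
        .configStop(paste(errs, collapse = "; "))
    cfg
}

#' Run the full inference pipeline on synthetic data
#'
#' Executes simulate -> differential abundance (both experiments) ->
#' concordance -> mediator screen -> expression simulation -> network
#' reconstruction -> regulator ranking, writing every stage output as TSV
#' under `outdir` plus a JSON run report with stage counts, timings, file
#' digests and the top candidates. Fully deterministic given the seed.
#'
#' @param config see [validateConfig()]; `config$simulation` entries are
#'   passed to [simulationConfig()] (the seed is taken from the top level).
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly.
#' @export
runPipeline <- function(config = NULL, outdir) {
    cfg <- validateConfig(config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    t0 <- proc.time()[["elapsed"]]
    timings <- list()
    tick <- function(stage) {
        t1 <- proc.time()[["elapsed"]]
        timings[[stage]] <<- round(t1 - t0, 3)
        t0 <<- t1
    }
    simArgs <- cfg$simulation
    simArgs$seed <- cfg$seed
    scfg <- do.call(simulationConfig, simArgs)

    sim <- simulateMicrobiomeExperiments(scfg)
    writeFeatureTable(sim$tableA, file.path(outdir, "table_A.tsv"))
    writeFeatureTable(sim$tableB, file.path(outdir, "table_B.tsv"))
    writeRecords(sim$meta, file.path(outdir, "metadata.tsv"))
    tick("simulate_microbiome")

    relA <- toRelativeAbundance(sim$tableA)
    relB <- toRelativeAbundance(sim$tableB)
    metaA <- sim$meta[sim$meta$experiment == "A", ]
    metaB <- sim$meta[sim$meta$experiment == "B", ]
    diffA <- differentialFeatures(relA, metaA, "perturbed", "control")
    diffB <- differentialFeatures(relB, metaB, "perturbed", "control")
    writeRecords(diffA, file.path(outdir, "differential_A.tsv"))
    writeRecords(diffB, file.path(outdir, "differential_B.tsv"))
    tick("differential")

    concord <- concordantFeatures(diffA, diffB, tau = cfg$fdr_tau)
    writeRecords(concord, file.path(outdir, "concordance.tsv"))
    tick("concordance")

    pertMeta <- sim$meta[sim$meta$group == "perturbed", ]
    pooled <- FeatureTable(cbind(abundances(relA), abundances(relB)),
                           kind = "relative")
    corr <- phenotypeCorrelations(
        pooled, pertMeta,
        features = concord$feature_id[concord$concordant],
        phenotypes = c("fasting_glucose", "auc_gtt"),
        method = cfg$correlation_method)
    candidates <- nominateMediators(concord, corr, alpha = cfg$alpha,
                                    meta = pertMeta,
                                    controlLabel = "control")
    writeRecords(candidates, file.path(outdir, "mediator_candidates.tsv"))
    tick("mediator_screen")

    expr <- simulateExpressionGroups(scfg)
    net <- buildNetwork(expr$exprGroups, expr$foldChanges,
                        pInd = cfg$p_ind, pComb = cfg$p_comb)
    writeRecords(networkNodes(net), file.path(outdir, "network_nodes.tsv"))
    writeRecords(networkEdges(net), file.path(outdir, "network_edges.tsv"))
    tick("network")

    ranks <- prioritizeRegulators(net, expr$exprGroups,
                                  expr$microbeByGroup, expr$foldChanges)
    writeRecords(ranks, file.path(outdir, "regulator_ranks.tsv"))
    tick("ranking")

    files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
    digests <- as.list(md5sum(sort(files)))
    names(digests) <- basename(names(digests))
    nCand <- sum(candidates$classification != "not_candidate")
    report <- list(
        seed = cfg$seed,
        config = cfg[setdiff(names(cfg), "simulation")],
        counts = list(
            features_tested = nrow(diffA),
            concordant = sum(concord$concordant),
            mediator_candidates = nCand,
            network_nodes = nrow(networkNodes(net)),
            network_edges = nrow(networkEdges(net)),
            genes_ranked = nrow(ranks)),
        membership_fraction = membershipFraction(net),
        top_candidates = utils::head(
            candidates$feature_id[candidates$classification !=
                                  "not_candidate"], 5L),
        top_ranked_genes = utils::head(ranks$gene_id, 5L),
        timings_sec = timings,
        file_digests = digests)
    write_json(report, file.path(outdir, "run_report.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(report)
}
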