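#' Default pipeline configuration
#'
#' All tunable parameters of the prioritization flow with their canonical
#' defaults: K = 5000 permutations, candidate threshold alpha = 0.01, grey
#' resolution ratio rho = 0.5, hard co-expression threshold r0 = 0.9,
#' strong-rewiring cutoff delta = 0.95, couplings tau1 = tau2 = 0.01,
#' external field at the 0.90 potential quantile, initial "+1" labels at
#' p <= 0.005, and top-20 reporting.
#'
#' @return named list of defaults; see \code{\link{runPipeline}}.
#' @export
pipelineDefaults <- function() {
    list(expr = NULL, meta = NULL, outdir = NULL,
         orientation = "genes_rows", log2Transform = FALSE, impute = FALSE,
         weeksPerStage = 3L, firstWeek = 3L, stages = NULL,
         K = 5000L, alpha = 0.01,
         rho = 0.5, r0 = 0.9, delta = 0.95,
         tau1 = 0.01, tau2 = 0.01, hQuantile = 0.90, initAlpha = 0.005,
         muBar = 2, a = 1, g = 1, d = 1, maxSweeps = 100L,
         topK = 20L, seed = 1L)
}

resolveConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    defaults <- pipelineDefaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    utils::modifyList(defaults, config, keep.null = TRUE)
}

#' Run the full gene-prioritization pipeline
#'
#' Wires the stages together: load expression + metadata, partition samples
#' into developmental stages, and per stage run the MV screen, build the
#' per-condition GCC matrices and the WGDCN over the candidates, fit the
#' HMRF by ICM and rank genes by posterior probability; finally assemble the
#' multilayer network over the stage-wise top-k lists with layer statistics
#' and the Jaccard overlap matrix. All outputs are TSV (plus GEXF for the
#' multilayer graph) under \code{outdir}, and a JSON run manifest records
#' parameters, seed and per-stage counts so any run can be reproduced.
#'
#' @param config named list overriding \code{\link{pipelineDefaults}}, or
#'   the path of a YAML file with the same keys. Unknown keys are rejected.
#'   Either \code{expr}/\code{meta} paths or a SummarizedExperiment passed
#'   via \code{se} is required.
#' @param se optionally, a ready-made SummarizedExperiment (e.g. from
#'   \code{\link{simulateExpression}}) instead of file paths.
#' @return invisible list with per-stage results (mv, network, fit,
#'   ranking), the multilayer summary and the manifest.
#' @export
runPipeline <- function(config = list(), se = NULL) {
    cfg <- resolveConfig(config)
    if (is.null(se)) {
        if (is.null(cfg$expr) || is.null(cfg$meta))
            stop("config must provide 'expr' and 'meta' paths (or pass ",
                 "'se' directly)")
        expr <- readExpression(cfg$expr, orientation = cfg$orientation,
                               impute = cfg$impute,
                               log2Transform = cfg$log2Transform)
        meta <- readSampleMetadata(cfg$meta)
        se <- makeRewireExperiment(expr, meta)
    }
    outdir <- cfg$outdir
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    emit <- function(df, name) {
        if (!is.null(outdir))
            writeResultTable(df, file.path(outdir, name))
    }

    wk <- SummarizedExperiment::colData(se)$week
    part <- partitionStages(wk, cfg$weeksPerStage, cfg$firstWeek)
    stages <- if (is.null(cfg$stages)) part$stages$stage else
        as.integer(cfg$stages)

    hCfg <- hmrfConfig(tau1 = cfg$tau1, tau2 = cfg$tau2,
                       delta = cfg$delta, hQuantile = cfg$hQuantile,
                       initAlpha = cfg$initAlpha, muBar = cfg$muBar,
                       a = cfg$a, g = cfg$g, d = cfg$d,
                       maxSweeps = cfg$maxSweeps)

    perStage <- list()
    counts <- list()
    for (s in stages) {
        res <- tryCatch(
            runStage(se, part, s, cfg, hCfg),
            error = function(e) stop("stage ", s, ": ", conditionMessage(e),
                                     call. = FALSE))
        emit(res$mv, sprintf("mv_stage%d.tsv", s))
        if (!is.null(outdir))
            exportNetwork(res$network,
                          file.path(outdir,
                                    sprintf("network_stage%d.tsv", s)))
        emit(res$ranking, sprintf("ranking_stage%d.tsv", s))
        perStage[[as.character(s)]] <- res
        counts[[as.character(s)]] <- list(
            n_samples = res$n_samples, n_candidates = res$n_candidates,
            n_edges = nrow(edges(res$network)),
            discrimination_mv = res$discrimination_mv,
            discrimination_hmrf = res$discrimination_hmrf)
    }

    multilayer <- NULL
    if (length(perStage) >= 2L) {
        layers <- lapply(perStage, function(r)
            layerSubnetwork(r$network, r$ranking$gene_id))
        ml <- assembleMultilayer(layers)
        stats <- do.call(rbind, lapply(ml@layers, layerStats))
        overlap <- jaccardOverlap(lapply(perStage, function(r)
            r$ranking$gene_id))
        if (!is.null(outdir)) {
            emit(stats, "layer_stats.tsv")
            writeResultTable(
                data.frame(stage = rownames(overlap), overlap,
                           check.names = FALSE),
                file.path(outdir, "overlap_matrix.tsv"))
            exportMultilayerGexf(ml, file.path(outdir, "multilayer.gexf"))
        }
        multilayer <- list(network = ml, stats = stats, overlap = overlap)
    }

    manifest <- list(
        package = "rewireHMRF",
        version = as.character(utils::packageVersion("rewireHMRF")),
        parameters = cfg[setdiff(names(cfg), c("expr", "meta", "outdir"))],
        inputs = list(expr = cfg$expr, meta = cfg$meta,
                      n_genes = nrow(se), n_samples = ncol(se)),
        stages = counts)
    if (!is.null(outdir))
        jsonlite::write_json(manifest,
                             file.path(outdir, "run_manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(stages = perStage, multilayer = multilayer,
                   manifest = manifest))
}

runStage <- function(se, part, s, cfg, hCfg) {
    sub <- stageSubset(se, part, s)
    mv <- mvScreen(sub, K = cfg$K, alpha = cfg$alpha, seed = cfg$seed)
    cand <- filterCandidates(mv, alpha = cfg$alpha)
    if (length(cand) < 2L)
        stop("fewer than 2 candidate genes pass the MV screen")
    x <- SummarizedExperiment::assay(sub, "expr")[cand, , drop = FALSE]
    y <- conditionResponse(sub)
    gccT <- gccMatrix(x[, y == 1L, drop = FALSE], rho = cfg$rho,
                      condition = "treatment")
    gccC <- gccMatrix(x[, y == 0L, drop = FALSE], rho = cfg$rho,
                      condition = "control")
    net <- buildWGDCN(gccT, gccC, r0 = cfg$r0, stage = s)
    pMv <- setNames(mv$p_mv, mv$gene_id)[cand]
    fit <- icmFit(net, pMv, config = hCfg, kPerms = cfg$K,
                  seed = cfg$seed)
    ranking <- rankGenes(fit, topK = min(cfg$topK, length(cand)))
    list(mv = mv, network = net, fit = fit, ranking = ranking,
         n_samples = ncol(sub), n_candidates = length(cand),
         discrimination_mv = discriminationAbility(pMv),
         discrimination_hmrf = discriminationAbility(posterior(fit)))
}
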