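# One full prioritization run on the default planted-signal design:
# MV screen -> per-condition GCC -> WGDCN -> ICM fit. Returns the scores
# needed to judge recovery of the planted (de + rewired) genes.
runPlantedPipeline <- function(seed, K = 500L, alpha = 0.01) {
    sim <- simulateExpression(syntheticDesign(seed = seed))
    mv <- suppressMessages(mvScreen(sim$se, K = K, alpha = alpha,
                                    seed = seed))
    cand <- filterCandidates(mv, alpha = alpha)
    x <- SummarizedExperiment::assay(sim$se, "expr")[cand, , drop = FALSE]
    y <- conditionResponse(sim$se)
    net <- buildWGDCN(
        gccMatrix(x[, y == 1, drop = FALSE], condition = "treatment"),
        gccMatrix(x[, y == 0, drop = FALSE], condition = "control"))
    pMv <- setNames(mv$p_mv, mv$gene_id)[cand]
    fit <- icmFit(net, pMv, kPerms = K)

    planted <- sim$truth$gene_id[sim$truth$class != "null"]
    score <- setNames(rep(0, nrow(mv)), mv$gene_id)  # screened-out -> 0
    score[cand] <- posterior(fit)
    k <- length(planted)
    top <- rankGenes(fit, topK = min(k, length(cand)))$gene_id
    list(truth = sim$truth, planted = planted, score = score,
         recovery = mean(planted %in% top),
         dMv = discriminationAbility(pMv),
         dHmrf = discriminationAbility(posterior(fit)))
}
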