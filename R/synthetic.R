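#' Design of a synthetic two-condition expression experiment
#'
#' Describes a genes x samples dataset with known ground truth: null genes
#' whose distribution ignores the condition, differentially expressed (DE)
#' genes whose treatment mean is shifted by \code{deShift} standard
#' deviations, and one rewired module whose genes share a latent factor with
#' pairwise correlation \code{corrTreat} under treatment but
#' \code{corrCtrl} under control. Module genes additionally receive a
#' treatment mean shift (\code{moduleShift}, default equal to
#' \code{deShift}): the screening stage tests each gene's marginal
#' conditional distribution, so a module whose genes were marginally null
#' would never reach the network stage — the module emulates responsive
#' genes whose co-expression also rewires.
#'
#' The default sizes mimic a single three-week developmental stage of a
#' two-condition field experiment: 200 genes (160 null / 20 DE / 20
#' module), 12 treated and 12 control samples.
#'
#' @param nNull,nDe,nModule gene counts per class (defaults 160/20/20).
#' @param nTreat,nCtrl sample counts (defaults 12/12).
#' @param deShift treatment mean shift of DE genes in SD units (default 2).
#' @param moduleShift treatment mean shift of module genes (default
#'   \code{deShift}).
#' @param corrTreat,corrCtrl pairwise latent-factor correlation of module
#'   genes per condition, in [0, 1) (defaults 0.9 / 0.1).
#' @param noiseSd standard deviation of the per-gene noise (default 1).
#' @param logNormal if TRUE (default) the Gaussian values are
#'   exponentiated, giving non-negative log-normal abundances as in
#'   processed RNA-seq data.
#' @param firstWeek first sampling week (default 3); samples cycle over
#'   three successive weeks so the dataset forms one stage.
#' @param seed integer seed; the same design yields bit-identical data.
#' @return validated design list.
#' @export
syntheticDesign <- function(nNull = 160L, nDe = 20L, nModule = 20L,
                            nTreat = 12L, nCtrl = 12L, deShift = 2,
                            moduleShift = deShift, corrTreat = 0.9,
                            corrCtrl = 0.1, noiseSd = 1,
                            logNormal = TRUE, firstWeek = 3L, seed = 1L) {
    stopifnot(nNull >= 0, nDe >= 0, nModule >= 0,
              nNull + nDe + nModule >= 2, nTreat >= 1, nCtrl >= 1,
              noiseSd > 0)
    if (corrTreat < 0 || corrTreat >= 1 || corrCtrl < 0 || corrCtrl >= 1)
        stop("module correlations must lie in [0, 1): a single shared ",
             "factor cannot realize negative pairwise correlation")
    list(nNull = as.integer(nNull), nDe = as.integer(nDe),
         nModule = as.integer(nModule), nTreat = as.integer(nTreat),
         nCtrl = as.integer(nCtrl), deShift = deShift,
         moduleShift = moduleShift, corrTreat = corrTreat,
         corrCtrl = corrCtrl, noiseSd = noiseSd,
         logNormal = isTRUE(logNormal), firstWeek = as.integer(firstWeek),
         seed = as.integer(seed))
}

#' Simulate a two-condition expression dataset with planted ground truth
#'
#' @param design list from \code{\link{syntheticDesign}}.
#' @return list with \code{se} (a SummarizedExperiment, assay "expr") and
#'   \code{truth} (data.frame gene_id / class / de_shift / module_id, class
#'   in null/de/rewired).
#' @export
simulateExpression <- function(design = syntheticDesign()) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(design$seed)
    nT <- design$nTreat
    nC <- design$nCtrl
    n <- nT + nC
    M <- design$nNull + design$nDe + design$nModule
    cond <- rep(c("treatment", "control"), c(nT, nC))
    weeks <- design$firstWeek + (c(seq_len(nT), seq_len(nC)) - 1L) %% 3L
    repl <- stats::ave(seq_len(n), paste(cond, weeks),
                       FUN = seq_along)
    sampleIds <- sprintf("%s_w%d_r%d", ifelse(cond == "treatment",
                                              "treat", "ctrl"),
                         weeks, repl)
    meta <- data.frame(sample_id = sampleIds, condition = cond,
                       week = weeks, replicate = repl,
                       stringsAsFactors = FALSE)

    cls <- rep(c("null", "de", "rewired"),
               c(design$nNull, design$nDe, design$nModule))
    shift <- ifelse(cls == "de", design$deShift,
                    ifelse(cls == "rewired", design$moduleShift, 0))
    geneIds <- sprintf("g%04d_%s", seq_len(M), cls)

    x <- matrix(rnorm(M * n), M, n)            # unit-variance noise
    if (design$nModule > 0L) {
        modRows <- which(cls == "rewired")
        fT <- rnorm(nT)
        fC <- rnorm(nC)
        lt <- sqrt(design$corrTreat)
        lc <- sqrt(design$corrCtrl)
        isT <- cond == "treatment"
        for (i in modRows) {
            x[i, isT] <- lt * fT + sqrt(1 - lt^2) * x[i, isT]
            x[i, !isT] <- lc * fC + sqrt(1 - lc^2) * x[i, !isT]
        }
    }
    x <- x * design$noiseSd
    x <- x + outer(shift * design$noiseSd,
                   as.numeric(cond == "treatment"))
    if (design$logNormal) x <- exp(x)
    dimnames(x) <- list(geneIds, sampleIds)

    truth <- data.frame(gene_id = geneIds, class = cls,
                        de_shift = shift,
                        module_id = ifelse(cls == "rewired", 1L,
                                           NA_integer_),
                        stringsAsFactors = FALSE)
    list(se = makeRewireExperiment(x, meta), truth = truth)
}

#' Deterministic hand-checkable fixture
#'
#' A 6-gene x 8-sample dataset (4 treatment / 4 control) with literal
#' values: a strongly condition-shifted gene, interchangeable-looking null
#' genes, a pair whose co-expression differs between conditions, and a
#' constant gene (its MV statistic is exactly 0). Useful in unit tests and
#' examples.
#'
#' @return a SummarizedExperiment with assay "expr".
#' @export
tinyFixture <- function() {
    vals <- matrix(c(
        8, 9, 10, 11,  1, 2, 3, 4,    # shifted under treatment
        5, 1,  4,  2,  3, 6, 2, 5,    # null
        1, 2,  3,  4,  4, 1, 3, 2,    # co-expressed with g4 in treatment
        2, 3,  4,  5,  1, 4, 2, 3,    # partner of g3
        3, 3,  3,  3,  3, 3, 3, 3,    # constant
        10, 2, 8,  4,  6, 7, 1, 9),   # null
        nrow = 6, byrow = TRUE)
    dimnames(vals) <- list(
        paste0("g", 1:6),
        c("treat_w3_r1", "treat_w3_r2", "treat_w4_r1", "treat_w4_r2",
          "ctrl_w3_r1", "ctrl_w3_r2", "ctrl_w4_r1", "ctrl_w4_r2"))
    meta <- data.frame(
        sample_id = colnames(vals),
        condition = rep(c("treatment", "control"), each = 4L),
        week = rep(c(3L, 3L, 4L, 4L), 2L),
        replicate = rep(c(1L, 2L, 1L, 2L), 2L),
        stringsAsFactors = FALSE)
    makeRewireExperiment(vals, meta)
}
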