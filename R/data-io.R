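#' Read a genes x samples expression matrix
#'
#' Reads a delimited text file (TSV or CSV, decided by extension unless
#' \code{sep} is given) with a header row of sample ids and a first column of
#' gene ids. Files stored transposed (samples as rows) are handled via
#' \code{orientation = "samples_rows"}.
#'
#' @param path file path.
#' @param orientation \code{"genes_rows"} (default) or \code{"samples_rows"}.
#' @param sep field separator; default inferred from the file extension
#'   (\code{.csv} is comma, anything else tab).
#' @param impute if TRUE, missing cells are replaced by the gene's mean over
#'   the remaining samples; by default missing values are an error.
#' @param log2Transform if TRUE, apply log2(x + 1) to all values after load.
#' @return numeric matrix, rows = genes, columns = samples, with dimnames.
#' @export
readExpression <- function(path,
                           orientation = c("genes_rows", "samples_rows"),
                           sep = NULL, impute = FALSE,
                           log2Transform = FALSE) {
    orientation <- match.arg(orientation)
    if (!file.exists(path) || file.size(path) == 0L)
        stop("expression file is missing or empty: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 2L || nrow(raw) < 1L)
        stop("expression file must have an id column plus data columns: ",
             path)
    ids <- as.character(raw[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate row ids in ", path, ": ",
             paste(unique(dup), collapse = ", "))
    vals <- raw[, -1L, drop = FALSE]
    if (anyDuplicated(colnames(vals)))
        stop("duplicate column ids in ", path, ": ",
             paste(unique(colnames(vals)[duplicated(colnames(vals))]),
                   collapse = ", "))
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (!is.numeric(v)) {
            suppressWarnings(num <- as.numeric(v))
            bad <- which(is.na(num) & !is.na(v) &
                         !v %in% c("NA", "NaN", ""))
            if (length(bad))
                stop("non-numeric value in ", path, " at row '",
                     ids[bad[1L]], "', column '", colnames(vals)[j], "'")
            vals[[j]] <- num
        }
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    if (orientation == "samples_rows") m <- t(m)
    if (anyNA(m)) {
        if (!impute) {
            bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
            stop("missing value at gene '", rownames(m)[bad[1L]],
                 "', sample '", colnames(m)[bad[2L]],
                 "' (set impute = TRUE for per-gene mean imputation)")
        }
        for (i in which(rowSums(is.na(m)) > 0L)) {
            mu <- mean(m[i, ], na.rm = TRUE)
            if (!is.finite(mu))
                stop("gene '", rownames(m)[i], "' has no observed values")
            m[i, is.na(m[i, ])] <- mu
        }
    }
    if (any(!is.finite(m)))
        stop("non-finite expression values in ", path)
    if (log2Transform) m <- log2(m + 1)
    if (nrow(m) < 2L || ncol(m) < 2L)
        stop("need at least 2 genes and 2 samples, got ",
             nrow(m), " x ", ncol(m))
    message("loaded expression matrix: ", nrow(m), " genes x ",
            ncol(m), " samples")
    m
}

#' Write an expression matrix as TSV (genes as rows)
#'
#' @param expr numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpression <- function(expr, path) {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV/CSV with columns \code{sample_id}, \code{condition}
#' (treatment/control), \code{week} (positive integer) and \code{replicate}
#' (integer >= 1).
#'
#' @param path file path.
#' @param sep field separator; inferred from extension when NULL.
#' @return data.frame with the four validated columns.
#' @export
readSampleMetadata <- function(path, sep = NULL) {
    if (!file.exists(path) || file.size(path) == 0L)
        stop("metadata file is missing or empty: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    meta <- read.delim(path, sep = sep, header = TRUE,
                       stringsAsFactors = FALSE)
    validateSampleMetadata(meta)
}

validateSampleMetadata <- function(meta) {
    need <- c("sample_id", "condition", "week", "replicate")
    missing <- setdiff(need, names(meta))
    if (length(missing))
        stop("metadata is missing column(s): ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample ids in metadata: ",
             paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                   collapse = ", "))
    if (!all(meta$condition %in% c("treatment", "control")))
        stop("condition must be 'treatment' or 'control'")
    if (any(!is.finite(meta$week)) || any(meta$week < 1) ||
        any(meta$week != round(meta$week)))
        stop("week must be a positive integer")
    if (any(!is.finite(meta$replicate)) || any(meta$replicate < 1))
        stop("replicate must be an integer >= 1")
    meta[need]
}

#' Bundle expression and metadata into a SummarizedExperiment
#'
#' Columns of the expression matrix are matched (and reordered) to the
#' metadata's \code{sample_id}; every sample must appear in both.
#'
#' @param expr genes x samples numeric matrix.
#' @param meta data.frame as returned by \code{\link{readSampleMetadata}}.
#' @return a \code{SummarizedExperiment} with assay \code{"expr"} and colData
#'   columns condition, week, replicate.
#' @export
makeRewireExperiment <- function(expr, meta) {
    meta <- validateSampleMetadata(as.data.frame(meta))
    if (!setequal(colnames(expr), meta$sample_id))
        stop("expression columns and metadata sample_id must match; ",
             "offenders: ",
             paste(c(setdiff(colnames(expr), meta$sample_id),
                     setdiff(meta$sample_id, colnames(expr))),
                   collapse = ", "))
    expr <- expr[, meta$sample_id, drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = expr),
        colData = S4Vectors::DataFrame(
            condition = meta$condition, week = as.integer(meta$week),
            replicate = as.integer(meta$replicate),
            row.names = meta$sample_id))
}

#' Binary response vector of a rewire experiment
#'
#' @param se SummarizedExperiment built by \code{makeRewireExperiment}.
#' @return integer vector, 1 for treatment samples and 0 for control.
#' @export
conditionResponse <- function(se) {
    as.integer(SummarizedExperiment::colData(se)$condition == "treatment")
}

#' Partition sampling weeks into contiguous developmental stages
#'
#' Stage s covers weeks firstWeek + (s-1) * weeksPerStage, ..,
#' firstWeek + s * weeksPerStage - 1. With the defaults (three-week stages
#' starting at week 3) weeks 3-17 fall into exactly five stages.
#'
#' @param weeks integer vector of observed sampling weeks.
#' @param weeksPerStage number of successive weeks per stage (default 3).
#' @param firstWeek first analyzed week (default 3).
#' @return list with \code{stageOfWeek} (named integer, one entry per
#'   distinct week) and \code{stages} (data.frame stage / week_min /
#'   week_max over the observed range).
#' @export
partitionStages <- function(weeks, weeksPerStage = 3L, firstWeek = 3L) {
    if (weeksPerStage < 1L) stop("weeksPerStage must be >= 1")
    weeks <- as.integer(weeks)
    if (any(weeks < firstWeek))
        stop("week(s) below firstWeek = ", firstWeek, ": ",
             paste(sort(unique(weeks[weeks < firstWeek])), collapse = ", "))
    uw <- sort(unique(weeks))
    stageOf <- (uw - firstWeek) %/% weeksPerStage + 1L
    names(stageOf) <- uw
    sIdx <- sort(unique(stageOf))
    stages <- data.frame(
        stage = sIdx,
        week_min = firstWeek + (sIdx - 1L) * weeksPerStage,
        week_max = firstWeek + sIdx * weeksPerStage - 1L)
    list(stageOfWeek = stageOf, stages = stages)
}

#' Restrict an experiment to the samples of one developmental stage
#'
#' @param se SummarizedExperiment from \code{makeRewireExperiment}.
#' @param partition result of \code{\link{partitionStages}}.
#' @param stage stage index to keep.
#' @return SummarizedExperiment restricted to the stage's samples (column
#'   order preserved).
#' @export
stageSubset <- function(se, partition, stage) {
    if (!stage %in% partition$stages$stage)
        stop("stage ", stage, " is not present in the partition")
    wk <- SummarizedExperiment::colData(se)$week
    stg <- partition$stageOfWeek[as.character(wk)]
    if (anyNA(stg))
        stop("sample week(s) not covered by the partition: ",
             paste(unique(wk[is.na(stg)]), collapse = ", "))
    keep <- which(stg == stage)
    sub <- se[, keep]
    cond <- SummarizedExperiment::colData(sub)$condition
    if (!any(cond == "treatment") || !any(cond == "control"))
        stop("stage ", stage, " lacks treatment or control samples; ",
             "per-condition co-expression cannot be computed")
    sub
}

#' Log2 fold changes between treatment and control means
#'
#' FC = (mean over treatment samples + epsilon) / (mean over control samples
#' + epsilon); the pseudo-count guards against division by, and logs of,
#' zero in sparse expression data.
#'
#' @param se SummarizedExperiment from \code{makeRewireExperiment}.
#' @param epsilon pseudo-count (default 1).
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
log2FoldChange <- function(se, epsilon = 1) {
    x <- SummarizedExperiment::assay(se, "expr")
    y <- conditionResponse(se)
    mt <- rowMeans(x[, y == 1L, drop = FALSE])
    mc <- rowMeans(x[, y == 0L, drop = FALSE])
    log2((mt + epsilon) / (mc + epsilon))
}

#' Classify genes into volcano-plot categories
#'
#' A gene is significantly up-/down-regulated when |log2 FC| exceeds
#' \code{fcCut} strictly and p < \code{pCut}; FC-only classes use
#' |log2 FC| >= fcCut with p >= pCut; P-only means p < pCut with
#' |log2 FC| < fcCut; everything else is NoDiff.
#'
#' @param log2Fc numeric vector of log2 fold changes.
#' @param pValue numeric vector of p-values in [0, 1].
#' @param fcCut log2 fold-change cutoff (default 1).
#' @param pCut p-value cutoff (default 0.05).
#' @return character vector over \code{c("sigUp", "sigDown", "FC_UpOnly",
#'   "FC_DownOnly", "P_Only", "NoDiff")}.
#' @export
classifyDEG <- function(log2Fc, pValue, fcCut = 1, pCut = 0.05) {
    if (length(log2Fc) != length(pValue))
        stop("log2Fc and pValue must have the same length")
    if (any(!is.finite(log2Fc)) || any(!is.finite(pValue)))
        stop("classifyDEG requires finite inputs")
    if (any(pValue < 0) || any(pValue > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep("NoDiff", length(log2Fc))
    sig <- pValue < pCut
    out[sig & log2Fc > fcCut] <- "sigUp"
    out[sig & log2Fc < -fcCut] <- "sigDown"
    fcOnly <- !sig & abs(log2Fc) >= fcCut
    out[fcOnly & log2Fc > 0] <- "FC_UpOnly"
    out[fcOnly & log2Fc <= 0] <- "FC_DownOnly"
    out[sig & abs(log2Fc) < fcCut] <- "P_Only"
    out
}

#' Differential-expression table
#'
#' Combines per-gene log2 fold changes with caller-supplied p-values (e.g.
#' from a two-sample test run elsewhere) into a table with the volcano
#' category of each gene.
#'
#' @param se SummarizedExperiment from \code{makeRewireExperiment}.
#' @param pValues named or positional numeric vector aligned to the genes.
#' @param fcCut,pCut cutoffs passed to \code{\link{classifyDEG}}.
#' @param epsilon pseudo-count for the fold change.
#' @return data.frame gene_id / log2_fc / p_value / category.
#' @export
degTable <- function(se, pValues, fcCut = 1, pCut = 0.05, epsilon = 1) {
    lfc <- log2FoldChange(se, epsilon = epsilon)
    if (!is.null(names(pValues))) {
        if (!setequal(names(pValues), names(lfc)))
            stop("pValues names must match the genes of 'se'")
        pValues <- pValues[names(lfc)]
    } else if (length(pValues) != length(lfc)) {
        stop("pValues must have one value per gene")
    }
    data.frame(gene_id = names(lfc), log2_fc = unname(lfc),
               p_value = unname(pValues),
               category = classifyDEG(lfc, pValues, fcCut, pCut),
               stringsAsFactors = FALSE)
}

#' Write a result table as TSV
#'
#' All tabular artifacts (candidate tables, rankings, layer statistics) are
#' written with a header row, tab separation and '.' as the decimal mark.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
writeResultTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
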