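#' @import methods
#' @importFrom stats qnorm dnorm dt quantile plogis rnorm setNames ave
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Grey-correlation matrix for one experimental condition
#'
#' Symmetric matrix of corrected grey correlation coefficients (GCCs) between
#' candidate genes, computed from the samples of a single condition
#' (treatment or control). Entries lie in (0, 1] with a unit diagonal; the
#' raw reference-dependent coefficients have been symmetrized as
#' (r_pq + r_qp) / 2.
#'
#' @slot values numeric matrix, genes x genes, dimnames = gene ids.
#' @slot condition character, \code{"treatment"} or \code{"control"}.
#' @exportClass GCCMatrix
setClass("GCCMatrix",
    representation(values = "matrix", condition = "character"))

setValidity("GCCMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v) || nrow(v) != ncol(v))
        msg <- c(msg, "'values' must be a square numeric matrix")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "'values' must carry identical gene ids on both dims")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene ids")
    if (any(!is.finite(v)) || any(v <= 0) || any(v > 1 + 1e-12))
        msg <- c(msg, "entries must be finite and in (0, 1]")
    if (max(abs(v - t(v))) > 1e-12)
        msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v) - 1) > 1e-12))
        msg <- c(msg, "diagonal must be 1")
    if (!object@condition %in% c("treatment", "control"))
        msg <- c(msg, "'condition' must be 'treatment' or 'control'")
    if (length(msg)) msg else TRUE
})

#' Weighted gene differential co-expression network
#'
#' Undirected graph over candidate genes in which an edge joins two genes
#' whose GCC crosses the hard threshold r0 in opposite directions between
#' treatment and control; the edge weight is the rewiring strength
#' |r_treat - r_control|. Isolated candidate genes remain as nodes.
#'
#' @slot geneIds character vector of node ids (unique).
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}; one row per unordered pair, no self-loops, weights > 0.
#' @slot stage integer scalar, developmental stage index (NA if unstaged).
#' @exportClass WGDCN
setClass("WGDCN",
    representation(geneIds = "character", edges = "data.frame",
                   stage = "integer"))

setValidity("WGDCN", function(object) {
    msg <- character()
    e <- object@edges
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "duplicate gene ids")
    if (!all(c("gene_a", "gene_b", "weight") %in% names(e)))
        msg <- c(msg, "edges need columns gene_a, gene_b, weight")
    else {
        if (nrow(e)) {
            if (any(e$gene_a == e$gene_b))
                msg <- c(msg, "self-loops are not allowed")
            if (!all(c(e$gene_a, e$gene_b) %in% object@geneIds))
                msg <- c(msg, "edge endpoints must be network nodes")
            if (any(!is.finite(e$weight)) || any(e$weight <= 0))
                msg <- c(msg, "edge weights must be finite and > 0")
            key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
            if (anyDuplicated(key))
                msg <- c(msg, "duplicate undirected edges")
        }
    }
    if (length(object@stage) != 1L)
        msg <- c(msg, "'stage' must be a single integer (possibly NA)")
    if (length(msg)) msg else TRUE
})

#' Fitted hidden Markov random field over a rewiring network
#'
#' Result of ICM inference on the Ising/HMRF model: per-gene evidence scores
#' xi = qnorm(1 - P_MV), converged association labels in {-1, +1}, the
#' initial association potentials and external field h, and the posterior
#' probability of association evaluated at the converged configuration.
#'
#' @slot geneIds character vector, length m.
#' @slot xi numeric, evidence scores.
#' @slot omega integer, converged labels (+1 associated / -1 not).
#' @slot potential numeric, association potentials at the initial labels.
#' @slot h numeric scalar, external-field parameter (quantile of potential).
#' @slot posterior numeric in [0, 1], P(omega_p = +1 | xi, omega_-p).
#' @slot converged logical, whether a sweep produced zero flips.
#' @slot sweeps integer, number of ICM sweeps performed.
#' @slot network the \linkS4class{WGDCN} the fit was computed on.
#' @slot config list of model parameters used.
#' @exportClass HMRFFit
setClass("HMRFFit",
    representation(geneIds = "character", xi = "numeric", omega = "integer",
                   potential = "numeric", h = "numeric",
                   posterior = "numeric", converged = "logical",
                   sweeps = "integer", network = "WGDCN", config = "list"))

setValidity("HMRFFit", function(object) {
    m <- length(object@geneIds)
    msg <- character()
    if (length(object@xi) != m || length(object@omega) != m ||
        length(object@potential) != m || length(object@posterior) != m)
        msg <- c(msg, "per-gene slots must all have length m")
    if (m && !all(object@omega %in% c(-1L, 1L)))
        msg <- c(msg, "labels must be -1 or +1")
    if (m && (any(object@posterior < 0) || any(object@posterior > 1)))
        msg <- c(msg, "posterior must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Multilayer differential co-expression network
#'
#' Stage-indexed stack of WGDCN subnetworks over each stage's top-ranked
#' genes, with interlayer edges joining the same gene across layer pairs.
#'
#' @slot layers named list of \linkS4class{WGDCN}, one per stage.
#' @slot interlayerEdges data.frame with columns \code{gene}, \code{stage_a},
#'   \code{stage_b}; one row per (gene, unordered layer pair).
#' @exportClass MultilayerNetwork
setClass("MultilayerNetwork",
    representation(layers = "list", interlayerEdges = "data.frame"))

setValidity("MultilayerNetwork", function(object) {
    msg <- character()
    if (!all(vapply(object@layers, is, logical(1), "WGDCN")))
        msg <- c(msg, "all layers must be WGDCN objects")
    if (!all(c("gene", "stage_a", "stage_b") %in%
             names(object@interlayerEdges)))
        msg <- c(msg, "interlayerEdges needs columns gene, stage_a, stage_b")
    if (length(msg)) msg else TRUE
})

## ---- generics ----

#' Gene identifiers of a network-analysis object
#' @param x a GCCMatrix, WGDCN, HMRFFit or MultilayerNetwork.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Edge table of a network
#' @param x a WGDCN.
#' @return data.frame with columns gene_a, gene_b, weight.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Posterior association probabilities
#' @param x an HMRFFit.
#' @return named numeric vector in [0, 1].
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))

#' Converged association labels
#' @param x an HMRFFit.
#' @return named integer vector in {-1, +1}.
#' @export
setGeneric("associationLabels", function(x)
    standardGeneric("associationLabels"))

#' @describeIn GCCMatrix gene ids
#' @param x object
#' @export
setMethod("geneIds", "GCCMatrix", function(x) rownames(x@values))

#' @describeIn WGDCN gene ids (nodes)
#' @param x object
#' @export
setMethod("geneIds", "WGDCN", function(x) x@geneIds)

#' @describeIn HMRFFit gene ids
#' @param x object
#' @export
setMethod("geneIds", "HMRFFit", function(x) x@geneIds)

#' @describeIn MultilayerNetwork union of layer gene ids
#' @param x object
#' @export
setMethod("geneIds", "MultilayerNetwork",
    function(x) unique(unlist(lapply(x@layers, geneIds), use.names = FALSE)))

#' @describeIn WGDCN edge table
#' @export
setMethod("edges", "WGDCN", function(x) x@edges)

#' @describeIn HMRFFit posterior probabilities
#' @export
setMethod("posterior", "HMRFFit",
    function(x) setNames(x@posterior, x@geneIds))

#' @describeIn HMRFFit converged labels
#' @export
setMethod("associationLabels", "HMRFFit",
    function(x) setNames(x@omega, x@geneIds))

#' GCC values
#' @param x a GCCMatrix.
#' @return symmetric numeric matrix of corrected GCCs.
#' @export
gccValues <- function(x) {
    stopifnot(is(x, "GCCMatrix"))
    x@values
}

#' Condition of a GCCMatrix
#' @param x a GCCMatrix.
#' @return "treatment" or "control".
#' @export
gccCondition <- function(x) {
    stopifnot(is(x, "GCCMatrix"))
    x@condition
}

setMethod("show", "GCCMatrix", function(object) {
    cat("GCCMatrix (", object@condition, "): ",
        nrow(object@values), " genes\n", sep = "")
    off <- object@values[upper.tri(object@values)]
    if (length(off))
        cat("  off-diagonal GCC range: [",
            format(min(off), digits = 4), ", ",
            format(max(off), digits = 4), "]\n", sep = "")
})

setMethod("show", "WGDCN", function(object) {
    cat("WGDCN: ", length(object@geneIds), " genes, ",
        nrow(object@edges), " rewiring edges",
        if (!is.na(object@stage)) paste0(" (stage ", object@stage, ")"),
        "\n", sep = "")
    if (nrow(object@edges))
        cat("  rewiring-strength range: [",
            format(min(object@edges$weight), digits = 4), ", ",
            format(max(object@edges$weight), digits = 4), "]\n", sep = "")
})

setMethod("show", "HMRFFit", function(object) {
    cat("HMRFFit: ", length(object@geneIds), " genes, ",
        sum(object@omega == 1L), " labelled associated; ",
        object@sweeps, " ICM sweep(s), ",
        if (object@converged) "converged" else "NOT converged",
        "\n  h = ", format(object@h, digits = 4), "\n", sep = "")
})

setMethod("show", "MultilayerNetwork", function(object) {
    cat("MultilayerNetwork: ", length(object@layers), " layers, ",
        nrow(object@interlayerEdges), " interlayer edges\n", sep = "")
    for (nm in names(object@layers)) {
        ly <- object@layers[[nm]]
        cat("  layer ", nm, ": ", length(ly@geneIds), " genes, ",
            nrow(ly@edges), " edges\n", sep = "")
    }
})
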