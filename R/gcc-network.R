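#' Grey correlation coefficients between genes of one condition
#'
#' With gene p as the reference sequence, the absolute differences
#' Delta_k(q) = |x_kp - x_kq| are compared against the global extremes of
#' |x_tp - x_ts| taken over every comparison gene s and sample t of the
#' condition:
#' r_pq = (1/n) sum_k (Dmin(p) + rho * Dmax(p)) / (Delta_k(q) + rho * Dmax(p)).
#' Because the reference gene itself belongs to the comparison set, Dmin(p)
#' is 0. The reference-dependent coefficients are symmetrized as
#' (r_pq + r_qp) / 2 and the diagonal set to 1.
#'
#' The grey coefficient needs no distributional assumptions and stays usable
#' at the handful of samples a single condition/stage provides, where Pearson
#' or Spearman correlations are unstable.
#'
#' @param expr genes x samples numeric matrix for one condition.
#' @param rho resolution ratio in (0, 1] (default 0.5); larger values damp
#'   the influence of the global maximum difference.
#' @param condition \code{"treatment"} or \code{"control"} tag.
#' @param pairwiseExtremes if TRUE, Dmin/Dmax are taken over the (p, q) pair
#'   only instead of the full gene set (non-default variant).
#' @return a \linkS4class{GCCMatrix}.
#' @export
gccMatrix <- function(expr, rho = 0.5,
                      condition = c("treatment", "control"),
                      pairwiseExtremes = FALSE) {
    condition <- match.arg(condition)
    if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
    if (is.null(rownames(expr))) stop("expr needs gene ids as rownames")
    m <- nrow(expr)
    n <- ncol(expr)
    if (m < 2L) stop("need at least 2 genes")
    if (n < 1L) stop("need at least 1 sample in the condition")
    D <- t(expr)                          # samples x genes
    r <- matrix(NA_real_, m, m, dimnames = list(rownames(expr),
                                                rownames(expr)))
    warned <- FALSE
    for (p in seq_len(m)) {
        diffs <- abs(D - D[, p])          # n x m, Delta_t(s) for reference p
        if (pairwiseExtremes) {
            dmax <- apply(diffs, 2L, max)
            dmin <- apply(diffs, 2L, min)
            zero <- dmax == 0
            if (any(zero) && !warned) {
                warning("degenerate pair(s) with zero range; GCC set to 1")
                warned <- TRUE
            }
            rp <- ifelse(zero, 1,
                         colMeans((rep(dmin, each = n) + rho *
                                   rep(dmax, each = n)) /
                                  (diffs + rep(rho * dmax, each = n))))
        } else {
            dmax <- max(diffs)
            dmin <- min(diffs)
            if (dmax == 0) {
                if (!warned) {
                    warning("all genes identical within the condition; ",
                            "GCC degenerates to 1")
                    warned <- TRUE
                }
                rp <- rep(1, m)
            } else {
                rp <- colMeans((dmin + rho * dmax) / (diffs + rho * dmax))
            }
        }
        r[p, ] <- rp
    }
    r <- (r + t(r)) / 2
    diag(r) <- 1
    new("GCCMatrix", values = r, condition = condition)
}

#' Build the weighted gene differential co-expression network
#'
#' Genes p and q are differentially co-expressed when their GCCs fall on
#' opposite sides of the hard threshold r0 between treatment and control,
#' i.e. (r_treat - r0) * (r_control - r0) <= 0. Each such pair receives an
#' undirected edge weighted by the rewiring strength
#' |r_treat - r_control|; pairs whose two GCCs both equal r0 exactly have
#' zero rewiring strength and are omitted (they would be inert in the Ising
#' model, whose couplings are weighted by the rewiring strength).
#'
#' @param gccTreat,gccCtrl \linkS4class{GCCMatrix} objects over the same
#'   genes (treatment / control).
#' @param r0 hard co-expression threshold in (0, 1) (default 0.9).
#' @param stage optional stage index stored on the network.
#' @return a \linkS4class{WGDCN}.
#' @export
buildWGDCN <- function(gccTreat, gccCtrl, r0 = 0.9, stage = NA_integer_) {
    stopifnot(is(gccTreat, "GCCMatrix"), is(gccCtrl, "GCCMatrix"))
    if (r0 <= 0 || r0 >= 1) stop("r0 must lie in (0, 1)")
    rt <- gccValues(gccTreat)
    rc <- gccValues(gccCtrl)
    if (!identical(rownames(rt), rownames(rc)))
        stop("treatment and control GCC matrices must share the same ",
             "genes in the same order")
    ids <- rownames(rt)
    ut <- upper.tri(rt)
    sel <- ut & ((rt - r0) * (rc - r0) <= 0) & (abs(rt - rc) > 0)
    idx <- which(sel, arr.ind = TRUE)
    edges <- data.frame(
        gene_a = ids[idx[, 1L]],
        gene_b = ids[idx[, 2L]],
        weight = abs(rt[sel] - rc[sel]),
        stringsAsFactors = FALSE)
    new("WGDCN", geneIds = ids, edges = edges,
        stage = as.integer(stage))
}

#' Construct a WGDCN directly from nodes and an edge table
#'
#' Mostly useful for tests and for re-importing exported networks.
#'
#' @param geneIds node ids.
#' @param edges data.frame gene_a / gene_b / weight (may have zero rows).
#' @param stage optional stage index.
#' @return a \linkS4class{WGDCN}.
#' @export
newWGDCN <- function(geneIds, edges = NULL, stage = NA_integer_) {
    if (is.null(edges) || !nrow(edges))
        edges <- data.frame(gene_a = character(), gene_b = character(),
                            weight = numeric(), stringsAsFactors = FALSE)
    edges <- data.frame(gene_a = as.character(edges$gene_a),
                        gene_b = as.character(edges$gene_b),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    new("WGDCN", geneIds = as.character(geneIds), edges = edges,
        stage = as.integer(stage))
}

#' Export a network as an edge list or GEXF
#'
#' The edge list is a three-column TSV (gene_a, gene_b, weight) with full
#' numeric precision so that export / re-import round-trips exactly. GEXF
#' output is readable by Gephi; node attributes (e.g. posterior
#' probabilities) can be attached for node sizing in external tools.
#'
#' @param net a \linkS4class{WGDCN}.
#' @param path output file.
#' @param format \code{"edgelist"} or \code{"gexf"}.
#' @param nodeAttrs optional named list of per-gene attribute vectors
#'   (names = attribute names; each vector named by gene id), written as GEXF
#'   node attvalues.
#' @export
exportNetwork <- function(net, path, format = c("edgelist", "gexf"),
                          nodeAttrs = NULL) {
    stopifnot(is(net, "WGDCN"))
    format <- match.arg(format)
    if (format == "edgelist") {
        e <- edges(net)
        e$weight <- sprintf("%.17g", e$weight)
        writeResultTable(e, path)
        return(invisible(path))
    }
    ids <- geneIds(net)
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<gexf xmlns="http://gexf.net/1.3" version="1.3">')
    w('  <graph defaultedgetype="undirected">')
    if (length(nodeAttrs)) {
        w('    <attributes class="node">')
        for (k in seq_along(nodeAttrs))
            w('      <attribute id="', k - 1L, '" title="',
              names(nodeAttrs)[k], '" type="double"/>')
        w('    </attributes>')
    }
    w('    <nodes>')
    for (g in ids) {
        if (length(nodeAttrs)) {
            w('      <node id="', g, '" label="', g, '">')
            w('        <attvalues>')
            for (k in seq_along(nodeAttrs)) {
                val <- nodeAttrs[[k]][g]
                if (!is.null(val) && !is.na(val))
                    w('          <attvalue for="', k - 1L, '" value="',
                      sprintf("%.17g", val), '"/>')
            }
            w('        </attvalues>')
            w('      </node>')
        } else {
            w('      <node id="', g, '" label="', g, '"/>')
        }
    }
    w('    </nodes>')
    w('    <edges>')
    e <- edges(net)
    for (i in seq_len(nrow(e)))
        w('      <edge id="', i - 1L, '" source="', e$gene_a[i],
          '" target="', e$gene_b[i], '" weight="',
          sprintf("%.17g", e$weight[i]), '"/>')
    w('    </edges>')
    w('  </graph>')
    w('</gexf>')
    invisible(path)
}

#' Re-import an exported edge-list network
#'
#' @param path TSV written by \code{\link{exportNetwork}}.
#' @param geneIds optional full node set (to preserve isolated genes); by
#'   default the nodes are the genes appearing in edges.
#' @param stage optional stage index.
#' @return a \linkS4class{WGDCN}.
#' @export
readNetworkEdgelist <- function(path, geneIds = NULL, stage = NA_integer_) {
    e <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
    if (is.null(geneIds))
        geneIds <- unique(c(e$gene_a, e$gene_b))
    newWGDCN(geneIds, e, stage = stage)
}

## igraph view of a WGDCN (isolated nodes preserved)
asIgraph <- function(net) {
    stopifnot(is(net, "WGDCN"))
    e <- edges(net)
    igraph::graph_from_data_frame(
        e[, c("gene_a", "gene_b", "weight")], directed = FALSE,
        vertices = data.frame(name = geneIds(net)))
}
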