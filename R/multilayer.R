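#' Induced subnetwork over a gene set
#'
#' Keeps the requested genes (ids absent from the network are skipped with a
#' warning) and every edge with both endpoints retained; weights are
#' preserved.
#'
#' @param net a \linkS4class{WGDCN}.
#' @param genes character vector of gene ids.
#' @return a \linkS4class{WGDCN} over the retained genes.
#' @export
layerSubnetwork <- function(net, genes) {
    stopifnot(is(net, "WGDCN"))
    genes <- as.character(genes)
    missing <- setdiff(genes, geneIds(net))
    if (length(missing))
        warning("gene(s) not in the network, skipped: ",
                paste(missing, collapse = ", "))
    keep <- intersect(geneIds(net), genes)  # network order preserved
    e <- edges(net)
    e <- e[e$gene_a %in% keep & e$gene_b %in% keep, , drop = FALSE]
    newWGDCN(keep, e, stage = net@stage)
}

#' Assemble a multilayer network from stage-wise subnetworks
#'
#' Each WGDCN becomes one layer; for every gene present in two layers an
#' interlayer edge joins its two copies, so a gene occurring in L layers
#' contributes choose(L, 2) interlayer edges.
#'
#' @param layers named list of \linkS4class{WGDCN} (names = stage labels) or
#'   an unnamed list whose stage slots are used as labels.
#' @return a \linkS4class{MultilayerNetwork}.
#' @export
assembleMultilayer <- function(layers) {
    if (length(layers) < 2L) stop("need at least 2 layers")
    if (is.null(names(layers))) {
        st <- vapply(layers, function(l) l@stage, integer(1))
        if (anyNA(st)) stop("unnamed layers must carry stage indices")
        names(layers) <- as.character(st)
    }
    if (anyDuplicated(names(layers))) stop("duplicate layer names")
    nms <- names(layers)
    inter <- list()
    for (i in seq_along(layers)) {
        for (j in seq_along(layers)) {
            if (i >= j) next
            shared <- intersect(geneIds(layers[[i]]), geneIds(layers[[j]]))
            if (length(shared))
                inter[[length(inter) + 1L]] <- data.frame(
                    gene = shared, stage_a = nms[i], stage_b = nms[j],
                    stringsAsFactors = FALSE)
        }
    }
    inter <- if (length(inter)) do.call(rbind, inter) else
        data.frame(gene = character(), stage_a = character(),
                   stage_b = character(), stringsAsFactors = FALSE)
    message("multilayer network: ", length(layers), " layers, ",
            nrow(inter), " interlayer edges")
    new("MultilayerNetwork", layers = layers, interlayerEdges = inter)
}

#' Topological summary of one network layer
#'
#' Standard unweighted statistics: density 2|E| / (|V| (|V| - 1)), average
#' degree 2|E| / |V|, average shortest-path length over connected pairs
#' only (finite even when the layer is disconnected), and average local
#' clustering coefficient with nodes of degree < 2 contributing 0 (set
#' \code{excludeLowDegree = TRUE} to average over degree >= 2 nodes only).
#'
#' @param net a \linkS4class{WGDCN}.
#' @param excludeLowDegree drop degree < 2 nodes from the clustering mean.
#' @return data.frame with columns stage, n_nodes, n_edges, density,
#'   avg_degree, avg_path_length, avg_clustering.
#' @export
layerStats <- function(net, excludeLowDegree = FALSE) {
    stopifnot(is(net, "WGDCN"))
    g <- asIgraph(net)
    nv <- igraph::vcount(g)
    ne <- igraph::ecount(g)
    dens <- if (nv >= 2L) 2 * ne / (nv * (nv - 1)) else 0
    avgDeg <- if (nv >= 1L) 2 * ne / nv else 0
    apl <- if (ne >= 1L)
        igraph::mean_distance(g, weights = NA, directed = FALSE,
                              unconnected = TRUE)
    else 0
    cl <- igraph::transitivity(g, type = "local", isolates = "zero")
    avgCl <- if (excludeLowDegree) {
        deg <- igraph::degree(g)
        if (any(deg >= 2L)) mean(cl[deg >= 2L]) else 0
    } else if (nv >= 1L) mean(cl) else 0
    data.frame(stage = net@stage, n_nodes = nv, n_edges = ne,
               density = dens, avg_degree = avgDeg,
               avg_path_length = apl, avg_clustering = avgCl)
}

#' Jaccard overlap matrix between gene sets
#'
#' Overlap(i, j) = |A_i intersect A_j| / |A_i union A_j|. Two empty sets
#' give a 0/0 ratio, reported as 0 with a warning; the diagonal is 1 for
#' non-empty sets.
#'
#' @param sets list of character vectors (named or not).
#' @return symmetric numeric matrix with entries in [0, 1].
#' @export
jaccardOverlap <- function(sets) {
    if (!length(sets)) stop("need at least one set")
    k <- length(sets)
    nms <- names(sets)
    if (is.null(nms)) nms <- as.character(seq_len(k))
    out <- matrix(0, k, k, dimnames = list(nms, nms))
    warned <- FALSE
    for (i in seq_len(k)) {
        for (j in i:k) {
            u <- length(union(sets[[i]], sets[[j]]))
            if (u == 0L) {
                if (!warned) {
                    warning("empty sets give an undefined 0/0 overlap; ",
                            "reported as 0")
                    warned <- TRUE
                }
                val <- 0
            } else {
                val <- length(intersect(sets[[i]], sets[[j]])) / u
            }
            out[i, j] <- out[j, i] <- val
        }
    }
    out
}

#' Export a multilayer network as GEXF
#'
#' Nodes are gene copies per layer (id "gene@layer") with the layer stored
#' as a node attribute; intralayer edges keep their rewiring weights and
#' interlayer edges join the copies of a shared gene.
#'
#' @param ml a \linkS4class{MultilayerNetwork}.
#' @param path output file.
#' @export
exportMultilayerGexf <- function(ml, path) {
    stopifnot(is(ml, "MultilayerNetwork"))
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<gexf xmlns="http://gexf.net/1.3" version="1.3">')
    w('  <graph defaultedgetype="undirected">')
    w('    <attributes class="node">')
    w('      <attribute id="0" title="layer" type="string"/>')
    w('    </attributes>')
    w('    <nodes>')
    for (nm in names(ml@layers)) {
        for (g in geneIds(ml@layers[[nm]])) {
            w('      <node id="', g, '@', nm, '" label="', g, '">')
            w('        <attvalues><attvalue for="0" value="', nm,
              '"/></attvalues>')
            w('      </node>')
        }
    }
    w('    </nodes>')
    w('    <edges>')
    eid <- 0L
    for (nm in names(ml@layers)) {
        e <- edges(ml@layers[[nm]])
        for (i in seq_len(nrow(e))) {
            w('      <edge id="', eid, '" source="', e$gene_a[i], '@', nm,
              '" target="', e$gene_b[i], '@', nm, '" weight="',
              sprintf("%.17g", e$weight[i]), '"/>')
            eid <- eid + 1L
        }
    }
    ie <- ml@interlayerEdges
    for (i in seq_len(nrow(ie))) {
        w('      <edge id="', eid, '" source="', ie$gene[i], '@',
          ie$stage_a[i], '" target="', ie$gene[i], '@', ie$stage_b[i],
          '"/>')
        eid <- eid + 1L
    }
    w('    </edges>')
    w('  </graph>')
    w('</gexf>')
    invisible(path)
}
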