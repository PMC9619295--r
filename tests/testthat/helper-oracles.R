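# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately follow the defining formulas term by
# term and share no code with the package internals.

# MV statistic by explicit tabulation of the empirical CDFs over all
# (class, observation) pairs.
oracleMVStatistic <- function(x, y) {
    n <- length(x)
    classes <- unique(y)
    total <- 0
    for (th in classes) {
        nTh <- sum(y == th)
        pTh <- nTh / n
        for (j in seq_len(n)) {
            Fth <- sum(x[y == th] <= x[j]) / nTh
            Fall <- sum(x <= x[j]) / n
            total <- total + pTh * (Fth - Fall)^2
        }
    }
    total
}

# Grey correlation matrix by a literal triple loop: reference gene p,
# comparison gene q, sample k; global extremes over all genes s and
# samples t, then symmetrization.
oracleGCC <- function(X, rho = 0.5) {
    m <- nrow(X)
    n <- ncol(X)
    raw <- matrix(NA_real_, m, m)
    for (p in seq_len(m)) {
        dAll <- c()
        for (s in seq_len(m))
            for (t in seq_len(n))
                dAll <- c(dAll, abs(X[p, t] - X[s, t]))
        dmin <- min(dAll)
        dmax <- max(dAll)
        for (q in seq_len(m)) {
            acc <- 0
            for (k in seq_len(n)) {
                dk <- abs(X[p, k] - X[q, k])
                acc <- acc + (dmin + rho * dmax) / (dk + rho * dmax)
            }
            raw[p, q] <- acc / n
        }
    }
    sym <- (raw + t(raw)) / 2
    diag(sym) <- 1
    dimnames(sym) <- list(rownames(X), rownames(X))
    sym
}

# Exact single-site conditional P(omega_p = +1 | xi, omega_-p) by
# enumerating every configuration of the Ising joint (explicit partition
# function) multiplied by the evidence likelihood.
oracleIsingConditional <- function(p, edgesDf, ids, omega, xi, h,
                                   tau1, tau2, delta, muBar, a, g, d) {
    m <- length(ids)
    ia <- match(edgesDf$gene_a, ids)
    ib <- match(edgesDf$gene_b, ids)
    s <- sqrt(d * (1 + 1 / a))
    logf1 <- stats::dt((xi - muBar) / s, df = g, log = TRUE) - log(s)
    logf0 <- stats::dnorm(xi, log = TRUE)
    configs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    logw <- numeric(nrow(configs))
    for (k in seq_len(nrow(configs))) {
        om <- configs[k, ]
        prior <- -h * sum(om == 1)
        if (nrow(edgesDf)) {
            bothPlus <- om[ia] == 1 & om[ib] == 1
            bothMinus <- om[ia] == -1 & om[ib] == -1 &
                edgesDf$weight > delta
            prior <- prior + tau1 * sum(edgesDf$weight[bothPlus]) -
                tau2 * sum(edgesDf$weight[bothMinus])
        }
        logw[k] <- prior + sum(ifelse(om == 1, logf1, logf0))
    }
    prob <- exp(logw - max(logw))
    prob <- prob / sum(prob)            # explicit Z
    rest <- setdiff(seq_len(m), p)
    match_rest <- apply(configs[, rest, drop = FALSE], 1L,
                        function(r) all(r == omega[rest]))
    num <- sum(prob[match_rest & configs[, p] == 1])
    den <- sum(prob[match_rest])
    num / den
}

# Unweighted graph statistics by hand: BFS all-pairs shortest paths and
# neighbor-pair triangle counting.
oracleGraphStats <- function(ids, edgesDf) {
    m <- length(ids)
    adj <- matrix(FALSE, m, m)
    if (nrow(edgesDf)) {
        ia <- match(edgesDf$gene_a, ids)
        ib <- match(edgesDf$gene_b, ids)
        adj[cbind(ia, ib)] <- TRUE
        adj[cbind(ib, ia)] <- TRUE
    }
    nE <- sum(adj) / 2
    density <- if (m >= 2) 2 * nE / (m * (m - 1)) else 0
    avgDeg <- if (m >= 1) 2 * nE / m else 0
    # BFS from every node
    dists <- c()
    for (src in seq_len(m)) {
        d <- rep(Inf, m)
        d[src] <- 0
        frontier <- src
        while (length(frontier)) {
            nxt <- c()
            for (v in frontier) {
                nb <- which(adj[v, ] & !is.finite(d))
                d[nb] <- d[v] + 1
                nxt <- c(nxt, nb)
            }
            frontier <- unique(nxt)
        }
        dists <- c(dists, d[-src])
    }
    finite <- dists[is.finite(dists)]
    apl <- if (length(finite)) mean(finite) else 0
    # local clustering, degree < 2 contributes 0
    cl <- numeric(m)
    for (v in seq_len(m)) {
        nb <- which(adj[v, ])
        k <- length(nb)
        if (k < 2) { cl[v] <- 0; next }
        links <- 0
        for (i in seq_along(nb))
            for (j in seq_along(nb))
                if (i < j && adj[nb[i], nb[j]]) links <- links + 1
        cl[v] <- 2 * links / (k * (k - 1))
    }
    list(density = density, avg_degree = avgDeg, avg_path_length = apl,
         avg_clustering = mean(cl))
}

# Random weighted network over m genes (edge probability pEdge, weights
# uniform on (0, 1)).
randomWGDCN <- function(m, pEdge = 0.4, seed = 1, stage = NA_integer_) {
    set.seed(seed)
    ids <- sprintf("n%02d", seq_len(m))
    pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < pEdge
    e <- data.frame(gene_a = ids[pairs[keep, 1]],
                    gene_b = ids[pairs[keep, 2]],
                    weight = runif(sum(keep), 0.01, 1),
                    stringsAsFactors = FALSE)
    newWGDCN(ids, e, stage = stage)
}
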