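#' HMRF model configuration
#'
#' Parameters of the Ising/hidden-Markov-random-field prioritization model.
#' \code{tau1} rewards edges joining two associated genes, \code{tau2}
#' penalizes strong edges (rewiring strength > \code{delta}) joining two
#' unassociated genes, and the external field h is set to the
#' \code{hQuantile} quantile of the association-potential vector computed at
#' the initial labels. \code{muBar}, \code{a}, \code{g}, \code{d} are the
#' Normal/Inverse-Gamma hyperparameters of the associated-gene evidence
#' model; their prior-predictive marginal is a Student-t with g degrees of
#' freedom, location muBar and squared scale d * (1 + 1/a).
#'
#' @param tau1,tau2 non-negative coupling parameters (defaults 0.01).
#' @param delta strong-rewiring cutoff in (0, 1) (default 0.95).
#' @param hQuantile quantile in (0, 1) defining h (default 0.90).
#' @param initAlpha p-value threshold for the initial "+1" labels
#'   (default 0.005, boundary inclusive).
#' @param muBar,a,g,d hyperparameters of the evidence prior (defaults 2, 1,
#'   1, 1).
#' @param maxSweeps maximum ICM sweeps (default 100).
#' @param pClamp clamp applied to p-values before the normal-score
#'   transform; NULL means 1 / (2 * K) with K the permutation count.
#' @param randomSweep if TRUE, each sweep visits genes in a seeded random
#'   order instead of the fixed ascending order.
#' @return list of validated parameters.
#' @export
hmrfConfig <- function(tau1 = 0.01, tau2 = 0.01, delta = 0.95,
                       hQuantile = 0.90, initAlpha = 0.005,
                       muBar = 2, a = 1, g = 1, d = 1,
                       maxSweeps = 100L, pClamp = NULL,
                       randomSweep = FALSE) {
    stopifnot(tau1 >= 0, tau2 >= 0, delta > 0, delta < 1,
              hQuantile > 0, hQuantile < 1, initAlpha > 0,
              a > 0, g > 0, d > 0, maxSweeps >= 1)
    if (!is.null(pClamp))
        stopifnot(pClamp > 0, pClamp < 0.5)
    list(tau1 = tau1, tau2 = tau2, delta = delta, hQuantile = hQuantile,
         initAlpha = initAlpha, muBar = muBar, a = a, g = g, d = d,
         maxSweeps = as.integer(maxSweeps), pClamp = pClamp,
         randomSweep = isTRUE(randomSweep))
}

#' Normal evidence scores from MV p-values
#'
#' xi_p = qnorm(1 - p) after clamping p into [clamp, 1 - clamp]; under the
#' null the p-value is Uniform(0, 1) so xi is standard normal, while small
#' p-values map to large positive scores. Clamping keeps xi finite when the
#' permutation p-value is exactly 0 or 1.
#'
#' @param pMv numeric vector of p-values in [0, 1].
#' @param clamp clamping constant in (0, 0.5); 1 / (2K) is the natural
#'   choice for K-permutation p-values.
#' @return numeric vector of finite evidence scores.
#' @export
normalScores <- function(pMv, clamp = 1e-4) {
    if (any(pMv < 0 | pMv > 1)) stop("p-values must lie in [0, 1]")
    stopifnot(clamp > 0, clamp < 0.5)
    qnorm(1 - pmin(pmax(pMv, clamp), 1 - clamp))
}

#' Initial association labels from MV p-values
#'
#' Candidates with p <= initAlpha start as "+1" (associated); the remaining
#' candidates (initAlpha < p <= 0.01) start as "-1". Calling this on genes
#' that never passed the candidate screen is a pipeline error.
#'
#' @param pMv p-values of the screened candidate genes.
#' @param initAlpha threshold (default 0.005, boundary inclusive).
#' @param screenAlpha the screen threshold the genes must satisfy
#'   (default 0.01).
#' @return integer vector of labels in {-1, +1}.
#' @export
initLabels <- function(pMv, initAlpha = 0.005, screenAlpha = 0.01) {
    if (any(pMv > screenAlpha))
        stop("initLabels received gene(s) with p_mv > ", screenAlpha,
             "; labels are only defined for screened candidates")
    ifelse(pMv <= initAlpha, 1L, -1L)
}

## adjacency as index/weight lists, aligned to geneIds(net)
adjacencyList <- function(net) {
    ids <- geneIds(net)
    m <- length(ids)
    e <- edges(net)
    ia <- match(e$gene_a, ids)
    ib <- match(e$gene_b, ids)
    nbr <- vector("list", m)
    wts <- vector("list", m)
    for (p in seq_len(m)) {
        nbr[[p]] <- integer()
        wts[[p]] <- numeric()
    }
    for (k in seq_len(nrow(e))) {
        nbr[[ia[k]]] <- c(nbr[[ia[k]]], ib[k])
        wts[[ia[k]]] <- c(wts[[ia[k]]], e$weight[k])
        nbr[[ib[k]]] <- c(nbr[[ib[k]]], ia[k])
        wts[[ib[k]]] <- c(wts[[ib[k]]], e$weight[k])
    }
    list(nbr = nbr, wts = wts, ids = ids)
}

#' Association potential of each gene
#'
#' Potential(p) = tau1 * sum of rewiring strengths to "+1"-labelled
#' neighbors + tau2 * sum of rewiring strengths > delta to "-1"-labelled
#' neighbors. Its upper quantile sets the external field h, encoding the
#' belief that genes with marginal p-values may still be associated.
#'
#' @param net a \linkS4class{WGDCN}.
#' @param omega label vector in {-1, +1} aligned to \code{geneIds(net)}.
#' @param config list from \code{\link{hmrfConfig}}.
#' @return numeric vector of potentials, one per gene.
#' @export
associationPotential <- function(net, omega, config = hmrfConfig()) {
    adj <- adjacencyList(net)
    m <- length(adj$ids)
    if (length(omega) != m)
        stop("omega must have one label per network gene")
    vapply(seq_len(m), function(p) {
        q <- adj$nbr[[p]]
        w <- adj$wts[[p]]
        config$tau1 * sum(w[omega[q] == 1L]) +
            config$tau2 * sum(w[omega[q] == -1L & w > config$delta])
    }, numeric(1))
}

#' External field h from the potential vector
#'
#' Empirical quantile of the association potentials using the default linear
#' interpolation between order statistics (type 7).
#'
#' @param potential numeric vector of potentials.
#' @param q quantile level (default 0.90).
#' @return numeric scalar h.
#' @export
computeH <- function(potential, q = 0.90) {
    if (!length(potential)) stop("potential vector is empty")
    unname(quantile(potential, probs = q, type = 7, names = FALSE))
}

#' Evidence densities under the null and associated models
#'
#' Under the null the evidence score is standard normal (f0). For associated
#' genes the score is normal with unknown (mu, sigma^2) carrying a
#' Normal/Inverse-Gamma prior (mu | sigma^2 ~ N(muBar, sigma^2 / a),
#' sigma^2 ~ InvGamma(g/2, g d/2)); integrating the parameters out gives the
#' prior-predictive marginal, a Student-t with g degrees of freedom,
#' location muBar and squared scale d (1 + 1/a), which is what f1 evaluates.
#'
#' @param xi numeric vector of evidence scores (finite).
#' @param config list from \code{\link{hmrfConfig}}.
#' @return list with numeric vectors \code{f0} and \code{f1} (> 0).
#' @export
evidenceDensities <- function(xi, config = hmrfConfig()) {
    if (any(!is.finite(xi))) stop("evidence scores must be finite")
    s <- sqrt(config$d * (1 + 1 / config$a))
    list(f0 = dnorm(xi),
         f1 = dt((xi - config$muBar) / s, df = config$g) / s)
}

logEvidenceRatio <- function(xi, config) {
    s <- sqrt(config$d * (1 + 1 / config$a))
    dt((xi - config$muBar) / s, df = config$g, log = TRUE) - log(s) -
        dnorm(xi, log = TRUE)
}

condLogit <- function(p, adj, omega, logRatio, h, config) {
    q <- adj$nbr[[p]]
    w <- adj$wts[[p]]
    logRatio[p] - h +
        config$tau1 * sum(w[omega[q] == 1L]) +
        config$tau2 * sum(w[omega[q] == -1L & w > config$delta])
}

#' Conditional posterior probability of association for one gene
#'
#' P(omega_p = +1 | xi, omega_-p) = plogis(Q) with
#' Q = ln(f1(xi_p) / f0(xi_p)) - h
#'   + tau1 * sum over "+1" neighbors of the rewiring strength
#'   + tau2 * sum over "-1" neighbors with rewiring strength > delta.
#' This is the exact single-site (Gibbs) conditional of the Ising prior
#' combined with the evidence likelihood; it is evaluated on the log scale
#' so large |Q| stays numerically stable.
#'
#' @param p gene index (into \code{geneIds(net)}) or gene id.
#' @param net a \linkS4class{WGDCN}.
#' @param omega current labels in {-1, +1}, aligned to the network genes.
#' @param xi evidence scores, same alignment.
#' @param h external field.
#' @param config list from \code{\link{hmrfConfig}}.
#' @return probability in [0, 1].
#' @export
conditionalPosterior <- function(p, net, omega, xi, h,
                                 config = hmrfConfig()) {
    adj <- adjacencyList(net)
    if (is.character(p)) p <- match(p, adj$ids)
    if (is.na(p) || p < 1L || p > length(adj$ids))
        stop("unknown gene index/id")
    logRatio <- logEvidenceRatio(xi, config)
    plogis(condLogit(p, adj, omega, logRatio, h, config))
}

#' Fit the HMRF by iterated conditional modes
#'
#' Runs the guilt-by-rewiring prioritization on a WGDCN: evidence scores are
#' the normal-score transforms of the MV p-values, labels are initialized
#' from the p-values (p <= initAlpha starts associated), the external field
#' h is the upper quantile of the association potentials at the initial
#' labels, and ICM then sweeps the genes in a fixed order, setting each
#' label to the mode of its conditional (posterior >= 0.5 means "+1") until
#' a full sweep makes no flip or maxSweeps is reached. Posterior
#' probabilities are the single-site conditionals at the converged
#' configuration. The procedure is deterministic; \code{seed} only matters
#' when \code{randomSweep} is enabled in the config.
#'
#' @param net a \linkS4class{WGDCN}.
#' @param pMv named numeric vector of MV p-values covering every network
#'   gene, or the data.frame returned by \code{\link{mvScreen}}.
#' @param config list from \code{\link{hmrfConfig}}.
#' @param kPerms permutation count behind the p-values; sets the default
#'   p-value clamp 1 / (2 * kPerms).
#' @param seed integer seed (used only for random sweep order).
#' @return an \linkS4class{HMRFFit}.
#' @export
icmFit <- function(net, pMv, config = hmrfConfig(), kPerms = 5000L,
                   seed = 1L) {
    stopifnot(is(net, "WGDCN"))
    if (is.data.frame(pMv)) {
        if (!is.null(pMv$k_perms) && nrow(pMv)) kPerms <- pMv$k_perms[1L]
        pMv <- setNames(pMv$p_mv, pMv$gene_id)
    }
    ids <- geneIds(net)
    if (is.null(names(pMv)) || !all(ids %in% names(pMv)))
        stop("pMv must be named and cover every network gene")
    pMv <- pMv[ids]
    clamp <- if (is.null(config$pClamp)) 1 / (2 * kPerms) else config$pClamp
    xi <- unname(normalScores(pMv, clamp = clamp))
    omega <- unname(initLabels(pMv, initAlpha = config$initAlpha))
    adj <- adjacencyList(net)
    m <- length(ids)
    pot <- associationPotential(net, omega, config)
    h <- computeH(pot, config$hQuantile)
    logRatio <- logEvidenceRatio(xi, config)

    converged <- FALSE
    sweeps <- 0L
    if (config$randomSweep) {
        old <- .Random.seed.save()
        on.exit(.Random.seed.restore(old))
        set.seed(seed)
    }
    while (sweeps < config$maxSweeps) {
        sweeps <- sweeps + 1L
        ord <- if (config$randomSweep) sample.int(m) else seq_len(m)
        flips <- 0L
        for (p in ord) {
            newLab <- if (condLogit(p, adj, omega, logRatio, h,
                                    config) >= 0) 1L else -1L
            if (newLab != omega[p]) {
                omega[p] <- newLab
                flips <- flips + 1L
            }
        }
        if (flips == 0L) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("ICM did not converge within ", config$maxSweeps,
                " sweeps; labels are from the last sweep")
    post <- plogis(vapply(seq_len(m), condLogit, numeric(1), adj = adj,
                          omega = omega, logRatio = logRatio, h = h,
                          config = config))
    new("HMRFFit", geneIds = ids, xi = unname(xi), omega = omega,
        potential = pot, h = h, posterior = post, converged = converged,
        sweeps = sweeps, network = net,
        config = c(config, list(pClampUsed = clamp)))
}

#' Rank genes by posterior probability of association
#'
#' Sorted by posterior descending; ties are broken by larger evidence score
#' xi, then lexicographically by gene id, so the ranking is deterministic.
#'
#' @param fit an \linkS4class{HMRFFit}.
#' @param topK number of genes to return (default 20); if larger than the
#'   gene count, all genes are returned with a warning.
#' @return data.frame gene_id / xi / label / potential / posterior / rank.
#' @export
rankGenes <- function(fit, topK = 20L) {
    stopifnot(is(fit, "HMRFFit"))
    m <- length(fit@geneIds)
    if (topK > m) {
        warning("topK = ", topK, " exceeds the number of genes (", m,
                "); returning all genes")
        topK <- m
    }
    ord <- order(-fit@posterior, -fit@xi, fit@geneIds)
    out <- data.frame(gene_id = fit@geneIds[ord], xi = fit@xi[ord],
                      label = fit@omega[ord],
                      potential = fit@potential[ord],
                      posterior = fit@posterior[ord],
                      rank = seq_len(m), stringsAsFactors = FALSE)
    out[seq_len(topK), , drop = FALSE]
}

#' Discrimination ability of a score vector
#'
#' R = U / m, the number of unique score values over the number of genes: a
#' ranking's resolution. Permutation p-values are lattice-valued (multiples
#' of 1/K) and tie heavily; HMRF posteriors vary continuously with the
#' network neighborhood, so their discrimination ability is typically much
#' higher.
#'
#' @param scores non-empty numeric vector.
#' @return value in (0, 1].
#' @export
discriminationAbility <- function(scores) {
    if (!length(scores)) stop("scores must be non-empty")
    length(unique(scores)) / length(scores)
}
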