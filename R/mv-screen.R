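#' Mean-variance (MV) index of dependence
#'
#' Model-free statistic for independence between a continuous variable x and
#' a categorical response y:
#' T = sum_theta sum_j p_theta (F_theta(x_j) - F(x_j))^2, where F_theta is
#' the empirical conditional CDF of x given y = theta (using <=), F the
#' marginal empirical CDF and p_theta the sample proportion of class theta.
#' T equals n times the sample MV index and is zero iff the conditional and
#' marginal empirical CDFs agree at every observed point.
#'
#' @param x numeric vector.
#' @param y vector of class labels, same length as x.
#' @return non-negative numeric scalar.
#' @export
mvStatistic <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have the same length")
    if (length(x) < 2L) stop("need at least 2 observations")
    if (any(!is.finite(x))) stop("x must be finite")
    n <- length(x)
    A <- outer(x, x, "<=")       # A[v, j] = I(x_v <= x_j)
    Fhat <- colMeans(A)
    total <- 0
    for (th in unique(y)) {
        idx <- y == th
        Fth <- colMeans(A[idx, , drop = FALSE])
        total <- total + mean(idx) * sum((Fth - Fhat)^2)
    }
    total
}

## deterministic per-gene seed so results do not depend on execution order
geneSeed <- function(seed, i) {
    s <- (as.numeric(seed) %% 2147483647) * 48271 + i * 9973
    as.integer(s %% 2147483629 + 1)
}

#' Permutation p-value for the MV test
#'
#' The observed statistic is compared with K statistics recomputed under
#' uniform random permutations of the response; the p-value is the fraction
#' of permuted statistics that reach or exceed the observed one, so it is a
#' multiple of 1/K in [0, 1] and can be exactly 0.
#'
#' @param x numeric vector.
#' @param y response labels.
#' @param K number of permutations (default 5000).
#' @param seed integer seed; the same seed gives a bit-identical p-value.
#' @return list with \code{t_obs}, \code{p_mv}, \code{k_perms}, \code{seed}.
#' @export
mvPermutationTest <- function(x, y, K = 5000L, seed) {
    if (missing(seed)) stop("a seed is required for reproducibility")
    if (K < 1L) stop("K must be >= 1")
    n <- length(x)
    tObs <- mvStatistic(x, y)
    A <- outer(x, x, "<=")
    Fhat <- colMeans(A)
    classes <- unique(y)
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    perm <- matrix(0L, K, n)
    for (k in seq_len(K)) perm[k, ] <- sample.int(n)
    tStar <- numeric(K)
    for (th in classes) {
        z <- as.numeric(y == th)        # class indicator, permuted by rows
        Zk <- matrix(z[perm], K, n)
        pTh <- mean(z)
        Fth <- (Zk %*% A) / sum(z)
        tStar <- tStar + pTh *
            rowSums((Fth - matrix(Fhat, K, n, byrow = TRUE))^2)
    }
    list(t_obs = tObs, p_mv = mean(tStar >= tObs - 1e-12),
         k_perms = as.integer(K), seed = as.integer(seed))
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' MV screening of all genes against the condition
#'
#' Runs the permutation MV test gene by gene against the binary treatment /
#' control response. Per-gene permutation streams are derived
#' deterministically from the master seed and the gene's position, so
#' results are reproducible and independent of execution order.
#'
#' @param x genes x samples numeric matrix, or a SummarizedExperiment built
#'   by \code{\link{makeRewireExperiment}}.
#' @param y binary response (ignored and derived from colData when x is a
#'   SummarizedExperiment).
#' @param K permutations per gene (default 5000).
#' @param alpha candidate threshold on the permutation p-value
#'   (default 0.01, boundary inclusive).
#' @param seed master integer seed.
#' @return data.frame gene_id / t_obs / p_mv / k_perms / retained.
#' @export
setGeneric("mvScreen", function(x, y, K = 5000L, alpha = 0.01, seed = 1L)
    standardGeneric("mvScreen"), signature = "x")

#' @describeIn mvScreen on a plain genes x samples matrix plus response
#' @export
setMethod("mvScreen", "matrix", function(x, y, K = 5000L, alpha = 0.01,
                                         seed = 1L) {
    if (ncol(x) != length(y))
        stop("response length must equal the number of samples")
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(x)))
    res <- vector("list", nrow(x))
    for (i in seq_len(nrow(x)))
        res[[i]] <- mvPermutationTest(x[i, ], y, K = K,
                                      seed = geneSeed(seed, i))
    out <- data.frame(
        gene_id = ids,
        t_obs = vapply(res, `[[`, numeric(1), "t_obs"),
        p_mv = vapply(res, `[[`, numeric(1), "p_mv"),
        k_perms = as.integer(K),
        stringsAsFactors = FALSE)
    out$retained <- out$p_mv <= alpha
    message("MV screen: ", sum(out$retained), " of ", nrow(out),
            " genes retained at alpha = ", alpha)
    out
})

#' @describeIn mvScreen on a SummarizedExperiment (response from colData)
#' @export
setMethod("mvScreen", "SummarizedExperiment",
    function(x, y, K = 5000L, alpha = 0.01, seed = 1L) {
        mvScreen(SummarizedExperiment::assay(x, "expr"),
                 conditionResponse(x), K = K, alpha = alpha, seed = seed)
    })

#' Candidate genes passing the MV screen
#'
#' @param results data.frame from \code{\link{mvScreen}}.
#' @param alpha p-value threshold (boundary inclusive, default 0.01).
#' @return character vector of retained gene ids, input order preserved.
#' @export
filterCandidates <- function(results, alpha = 0.01) {
    if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
    keep <- results$gene_id[results$p_mv <= alpha]
    if (!length(keep))
        warning("no genes pass the MV screen at alpha = ", alpha)
    keep
}
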