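test_that("normal scores transform p-values with finite clamping", {
    expect_equal(normalScores(0.5), 0)
    # independent numeric inverse-CDF check of the 0.975 quantile
    expect_equal(normalScores(0.025), 1.959964, tolerance = 1e-6)
    z <- normalScores(c(0, 1), clamp = 1e-4)
    expect_true(all(is.finite(z)))
    expect_equal(z[1], qnorm(1 - 1e-4))
    expect_error(normalScores(1.5), "\\[0, 1\\]")
})

test_that("initial labels split candidates at the init threshold", {
    expect_equal(initLabels(c(0.005, 0.008, 0.0002, 0.01)),
                 c(1L, -1L, 1L, -1L))
    expect_equal(initLabels(rep(0.001, 5)), rep(1L, 5))
    expect_error(initLabels(c(0.005, 0.02)), "screened candidates")
})

test_that("association potential sums the labelled neighbor contributions", {
    net <- newWGDCN(c("gA", "gB", "gC", "gD"),
                    data.frame(gene_a = c("gA", "gA"),
                               gene_b = c("gB", "gC"),
                               weight = c(0.5, 0.96)))
    cfg <- hmrfConfig()   # tau1 = tau2 = 0.01, delta = 0.95
    pot <- associationPotential(net, c(-1L, 1L, -1L, 1L), cfg)
    expect_equal(pot[4], 0)                # gD isolated -> empty sums
    expect_equal(pot[2], 0)                # gB's only neighbor gA is -1,
                                           # weight 0.5 fails > delta
    # one +1 neighbor of weight 0.5 -> tau1 * 0.5
    pot2 <- associationPotential(net, c(1L, -1L, -1L, -1L), cfg)
    expect_equal(pot2[2], 0.005)
    # gA: +1 neighbor gB (0.5) plus strong -1 neighbor gC (0.96 > delta)
    expect_equal(pot[1], 0.01 * 0.5 + 0.01 * 0.96)
    pot3 <- associationPotential(net, c(-1L, -1L, -1L, -1L), cfg)
    expect_equal(pot3[1], 0.01 * 0.96)     # only the strong edge counts
})

test_that("external field h uses the documented quantile convention", {
    expect_equal(computeH(rep(0, 10)), 0)
    pot <- 0.01 * (1:100)
    # type-7: 1 + 0.9 * 99 = 90.1 -> linear interpolation between order
    # statistics 90 and 91
    expect_equal(computeH(pot, 0.90), 0.901)
    # independent sort-based check
    srt <- sort(pot)
    idx <- 1 + 0.9 * (length(srt) - 1)
    expect_equal(computeH(pot, 0.90),
                 srt[floor(idx)] + (idx - floor(idx)) *
                     (srt[ceiling(idx)] - srt[floor(idx)]))
    expect_equal(computeH(pot, 1), 1)
    expect_error(computeH(numeric(0)), "empty")
})

test_that("evidence densities are the N(0,1) null and Student-t marginal", {
    cfg <- hmrfConfig()
    d0 <- evidenceDensities(0, cfg)
    expect_equal(d0$f0, 1 / sqrt(2 * pi))
    # at the location, f1 is the t mode density scaled by 1/s
    s <- sqrt(cfg$d * (1 + 1 / cfg$a))
    dMu <- evidenceDensities(cfg$muBar, cfg)
    expect_equal(dMu$f1, dt(0, df = cfg$g) / s)
    # the prior-predictive marginal integrates to 1
    area <- integrate(function(z) evidenceDensities(z, cfg)$f1,
                      -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(area, 1, tolerance = 1e-6)
    expect_error(evidenceDensities(Inf, cfg), "finite")
})

test_that("conditional posterior is 0.5 when evidence and field vanish", {
    cfg <- hmrfConfig()
    # xi where f1 crosses f0, so ln(f1/f0) = 0
    xiStar <- uniroot(function(z) {
        dd <- evidenceDensities(z, cfg)
        log(dd$f1) - log(dd$f0)
    }, c(0, 3), tol = 1e-12)$root
    net <- newWGDCN(c("gA", "gB"))   # no edges
    p <- conditionalPosterior("gA", net, omega = c(1L, 1L),
                              xi = c(xiStar, 0), h = 0, config = cfg)
    expect_equal(p, 0.5, tolerance = 1e-9)
    # logistic monotonicity towards 1 for large evidence
    ps <- vapply(c(2.5, 3, 3.5, 6, 20), function(z)
        conditionalPosterior("gA", net, c(1L, 1L), c(z, 0), 0, cfg),
        numeric(1))
    expect_true(all(diff(ps) > 0))
    expect_gt(ps[5], 1 - 1e-6)
})

test_that("single-site conditionals match exhaustive Ising enumeration", {
    cfg <- hmrfConfig()
    set.seed(77)
    for (rep in 1:12) {
        m <- sample(3:7, 1)
        net <- randomWGDCN(m, pEdge = 0.5, seed = 1000 + rep)
        # weights partly above delta so the tau2 branch is exercised
        e <- edges(net)
        if (nrow(e)) {
            e$weight[seq_len(nrow(e)) %% 3 == 0] <-
                runif(sum(seq_len(nrow(e)) %% 3 == 0), 0.96, 1)
            net <- newWGDCN(geneIds(net), e)
        }
        xi <- rnorm(m, mean = 2)
        omega <- sample(c(-1L, 1L), m, replace = TRUE)
        h <- runif(1, 0, 0.05)
        for (p in seq_len(m)) {
            got <- conditionalPosterior(p, net, omega, xi, h, cfg)
            want <- oracleIsingConditional(
                p, edges(net), geneIds(net), omega, xi, h,
                cfg$tau1, cfg$tau2, cfg$delta,
                cfg$muBar, cfg$a, cfg$g, cfg$d)
            expect_equal(got, want, tolerance = 1e-10)
        }
    }
})

test_that("both conditional branches sum to one", {
    cfg <- hmrfConfig()
    net <- randomWGDCN(6, pEdge = 0.5, seed = 4)
    xi <- rnorm(6, 2)
    omega <- rep(c(1L, -1L), 3)
    for (p in 1:6) {
        pPlus <- conditionalPosterior(p, net, omega, xi, 0.02, cfg)
        # P(-1 | .) computed independently from the enumerated joint
        pMinusOracle <- 1 - oracleIsingConditional(
            p, edges(net), geneIds(net), omega, xi, 0.02,
            cfg$tau1, cfg$tau2, cfg$delta, cfg$muBar, cfg$a, cfg$g, cfg$d)
        expect_equal(pPlus + pMinusOracle, 1, tolerance = 1e-10)
    }
})

test_that("ICM converges to a fixed point of the conditional modes", {
    set.seed(12)
    for (rep in 1:8) {
        m <- sample(5:15, 1)
        net <- randomWGDCN(m, pEdge = 0.3, seed = 500 + rep)
        pMv <- setNames(round(runif(m, 0, 0.01), 4), geneIds(net))
        fit <- icmFit(net, pMv, kPerms = 1000L)
        expect_true(fit@converged)
        expect_lte(fit@sweeps, hmrfConfig()$maxSweeps)
        # at convergence each label is the mode of its own conditional
        expect_equal(fit@omega == 1L, fit@posterior >= 0.5)
        expect_true(all(fit@posterior >= 0 & fit@posterior <= 1))
    }
})

test_that("ICM posteriors are monotone in the evidence score", {
    # raising one gene's evidence (lowering its p-value) never lowers its
    # posterior; checked over the operational range of screened candidates
    net <- randomWGDCN(6, pEdge = 0.5, seed = 9)
    base <- setNames(rep(0.008, 6), geneIds(net))
    ps <- c(0.01, 0.008, 0.005, 0.002, 0.001, 1e-4)
    post <- vapply(ps, function(p) {
        pm <- base
        pm["n03"] <- p
        posterior(icmFit(net, pm, kPerms = 5000L))[["n03"]]
    }, numeric(1))
    expect_true(all(diff(post) >= -1e-12))
})

test_that("isolated genes decouple and symmetric genes tie", {
    cfg <- hmrfConfig()
    # empty edge set: posterior = plogis(ln f1/f0 - h) per gene
    net <- newWGDCN(c("gA", "gB", "gC"))
    pMv <- c(gA = 0.001, gB = 0.006, gC = 0.01)
    fit <- icmFit(net, pMv, config = cfg, kPerms = 1000L)
    clamp <- 1 / 2000
    xi <- qnorm(1 - pmax(pMv, clamp))
    dd <- evidenceDensities(xi, cfg)
    expect_equal(unname(posterior(fit)),
                 unname(plogis(log(dd$f1 / dd$f0) - fit@h)),
                 tolerance = 1e-12)
    # two genes joined by one edge with identical evidence: symmetric fit
    net2 <- newWGDCN(c("gA", "gB"),
                     data.frame(gene_a = "gA", gene_b = "gB",
                                weight = 0.4))
    fit2 <- icmFit(net2, c(gA = 0.004, gB = 0.004), kPerms = 1000L)
    expect_equal(posterior(fit2)[["gA"]], posterior(fit2)[["gB"]])
})

test_that("ranking is deterministic with documented tie-breaks", {
    fit <- new("HMRFFit",
               geneIds = c("gB", "gA", "gC", "gD"),
               xi = c(2, 2, 3, 2), omega = c(1L, 1L, 1L, -1L),
               potential = rep(0, 4), h = 0,
               posterior = c(0.9, 0.9, 0.9, 0.2),
               converged = TRUE, sweeps = 1L,
               network = newWGDCN(c("gB", "gA", "gC", "gD")),
               config = list())
    r <- rankGenes(fit, topK = 4)
    # tie on posterior: larger xi first, then lexicographic id
    expect_equal(r$gene_id, c("gC", "gA", "gB", "gD"))
    expect_warning(rAll <- rankGenes(fit, topK = 10), "exceeds")
    expect_equal(nrow(rAll), 4L)
    expect_equal(formals(rankGenes)$topK, 20L)
})

test_that("discrimination ability counts unique score values", {
    expect_equal(discriminationAbility(c(0.1, 0.2, 0.3)), 1)
    expect_equal(discriminationAbility(rep(0.5, 4)), 1 / 4)
    expect_equal(discriminationAbility(c(0.1, 0.1, 0.2, 0.3)), 0.75)
    expect_error(discriminationAbility(numeric(0)), "non-empty")
})
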