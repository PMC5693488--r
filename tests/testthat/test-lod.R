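test_that("concordance curves score ensembles against the parent label", {
    reps <- fixtureRepCounts()
    model <- fixtureModel()
    ens <- simulateMixtureGrid(reps, "uip_tbb", "nonuip_slb", c(0, 1),
                               depth = 2e4, nSimulations = 30, seed = 5)
    curve <- concordanceCurve(ens, model, "UIP")
    expect_identical(curve$fraction, c(0, 1))
    expect_identical(curve$concordance[1], 1)  # pure parent
    expect_identical(curve$concordance[2], 0)  # pure opposite-class diluent
    expect_identical(curve$n, c(30L, 30L))

    expect_error(concordanceCurve(ens[1], model, "UIP"), "2 grid points")
})

test_that("the 90%-rule estimator matches step, analytic and scan oracles", {
    # noise-free step curve
    grid <- seq(0, 1, 0.05)
    step <- data.frame(fraction = grid,
                       concordance = as.numeric(grid <= 0.5), n = 100L)
    est <- estimateLod(step)
    expect_identical(lodValue(est), 0.5)
    expect_identical(est@flag, "ok")

    # analytic Gaussian boundary curve: c(f) = Phi((1 - 2 f) / 0.1)
    fine <- seq(0, 1, 0.001)
    analytic <- data.frame(fraction = fine,
                           concordance = pnorm((1 - 2 * fine) / 0.1),
                           n = 1000L)
    fStar <- (1 - 0.1 * qnorm(0.9)) / 2  # 0.43592
    expect_lt(abs(lodValue(estimateLod(analytic)) - fStar), 0.001)

    # saturated and empty cases
    sat <- data.frame(fraction = grid, concordance = 0.95, n = 10L)
    expect_identical(lodValue(estimateLod(sat)), 1)
    expect_identical(estimateLod(sat)@flag, "saturated")
    low <- data.frame(fraction = grid, concordance = 0.2, n = 10L)
    expect_identical(lodValue(estimateLod(low)), 0)
    expect_identical(estimateLod(low)@flag, "none_above_threshold")

    # brute-force scan agreement on deterministic monotone curves
    scanLod <- function(curve, thr)
        if (!any(curve$concordance >= thr)) 0 else
            max(curve$fraction[curve$concordance >= thr])
    set.seed(8)
    for (i in 1:20) {
        cv <- sort(runif(21), decreasing = TRUE)
        curve <- data.frame(fraction = grid, concordance = cv, n = 50L)
        thr <- runif(1, 0.6, 0.99)
        expect_identical(lodValue(estimateLod(curve, thr)),
                         scanLod(curve, thr))
    }
})

test_that("the LOD is non-increasing in the concordance threshold", {
    grid <- seq(0, 1, 0.05)
    set.seed(31)
    for (i in 1:20) {
        cv <- pmin(1, pmax(0, pnorm((0.5 - grid) / 0.15) +
                                rnorm(length(grid), 0, 0.05)))
        curve <- data.frame(fraction = grid, concordance = cv, n = 200L)
        lods <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.95, 0.99),
                       function(t) lodValue(estimateLod(curve, t)),
                       numeric(1))
        expect_true(all(diff(lods) <= 1e-12))
    }
})

test_that("bootstrap CIs are seeded and degenerate correctly", {
    grid <- seq(0, 1, 0.05)
    step <- data.frame(fraction = grid,
                       concordance = as.numeric(grid <= 0.5), n = 500L)
    ci <- lodBootstrapCi(step, nBootstrap = 200, seed = 1)
    expect_identical(unname(lodCI(ci)), c(0.5, 0.5))  # zero-noise: width 0

    noisy <- data.frame(fraction = grid,
                        concordance = pnorm((0.5 - grid) / 0.1), n = 200L)
    c1 <- lodBootstrapCi(noisy, nBootstrap = 300, seed = 7)
    c2 <- lodBootstrapCi(noisy, nBootstrap = 300, seed = 7)
    expect_identical(lodCI(c1), lodCI(c2))
    expect_lte(c1@lower, lodValue(c1))
    expect_gte(c1@upper, lodValue(c1))

    expect_error(lodBootstrapCi(noisy, nBootstrap = 10, seed = 1),
                 "nBootstrap")
})

test_that("spline crossings locate the boundary on lines and flag misses", {
    # exact line s(f) = 1 - 2 f crosses 0 at f = 0.5
    f5 <- c(0, 0.25, 0.5, 0.75, 1)
    est <- splineCrossing(f5, 1 - 2 * f5)
    expect_identical(est@flag, "ok")
    expect_lt(abs(lodValue(est) - 0.5), 1e-3)

    # all scores on the parent side: flagged, no estimate
    miss <- splineCrossing(f5, 2 + f5 * 0.1)
    expect_identical(miss@flag, "no_crossing")
    expect_true(is.na(lodValue(miss)))

    # noisy line recovers the known root
    set.seed(12)
    f9 <- seq(0, 1, length.out = 9)
    noisy <- splineCrossing(f9, 1 - 2 * f9 + rnorm(9, 0, 0.05))
    expect_lt(abs(lodValue(noisy) - 0.5), 0.05)

    expect_error(splineCrossing(c(0, 0.5, 1), c(1, 0, -1)), "4 distinct")
})
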