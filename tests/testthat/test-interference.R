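test_that("marker proportions behave as count arithmetic", {
    panel <- fixturePanel()
    k <- setNames(rep(0, length(geneIds(panel))), geneIds(panel))
    k[markerGene(panel)] <- 70
    k[geneIds(panel)[5]] <- 930
    expect_identical(markerProportion(k, panel), 0.07)
    expect_error(markerProportion(k * 0, panel), "zero total")

    cfg <- fixtureConfig()
    pr <- fixtureProfiles()
    tbb <- simulateCounts(pr$uip_tbb, cfg, seed = 31, depth = 1e5)
    expect_lt(abs(markerProportion(tbb, panel) - 0.003), 0.002)
    blood <- simulateCounts(pr$blood, cfg, seed = 31, depth = 1e5)
    expect_lt(abs(markerProportion(blood, panel) - 0.3075), 0.02)
})

test_that("implied pure-blood fraction inverts linear mixing exactly", {
    x <- impliedPureBloodFraction(0.003, 0.07, 0.22)
    expect_equal(as.numeric(x), 0.3075, tolerance = 1e-3)
    expect_false(attr(x, "inconsistent"))
    expect_gt(as.numeric(x), 0.17)           # above the pure-blood bound
    expect_gt(as.numeric(x) / 0.003, 50)     # >= 50-fold enrichment

    expect_equal(as.numeric(impliedPureBloodFraction(0.01, 0.01, 0.4)),
                 0.01, tolerance = 1e-12)    # no enrichment
    expect_equal(as.numeric(impliedPureBloodFraction(0.01, 0.42, 1)),
                 0.42, tolerance = 1e-12)    # pure diluent

    expect_warning(bad <- impliedPureBloodFraction(0, 0.9, 0.5),
                   "inconsistent")
    expect_true(attr(bad, "inconsistent"))

    # inversion is exact for any forward-mixed (b, x, f)
    set.seed(6)
    for (i in 1:25) {
        b <- runif(1, 0, 0.05); x <- runif(1, 0.1, 0.9)
        f <- runif(1, 0.01, 1)
        m <- f * x + (1 - f) * b
        expect_equal(as.numeric(impliedPureBloodFraction(b, m, f)), x,
                     tolerance = 1e-9)
    }
})

test_that("marker proportion of a mixture is linear in the fraction", {
    reps <- fixtureRepCounts()
    panel <- fixturePanel()
    mkP <- markerProportion(reps[, "uip_tbb"], panel)
    mkD <- markerProportion(reps[, "blood"], panel)
    for (f in c(0.1, 0.22, 0.5, 0.9)) {
        p <- mixProportions(reps[, "uip_tbb"], reps[, "blood"], f)
        expect_equal(unname(p[markerGene(panel)]),
                     (1 - f) * mkP + f * mkD, tolerance = 1e-12)
    }
})

test_that("blood titration reports scores, marker levels and a tolerance", {
    reps <- fixtureRepCounts()
    bt <- bloodTitration(reps, "uip_tbb", "blood", seq(0, 1, 0.1),
                         fixtureModel(), fixturePanel(), depth = 2e4,
                         nSimulations = 40, nBootstrap = 120, seed = 13)
    expect_s4_class(bt$lod, "LODEstimate")
    expect_identical(bt$reference_call, "UIP")
    expect_gt(lodValue(bt$lod), 0)

    # undiluted level scores like the parent
    parent <- scoreCounts(fixtureModel(), reps[, "uip_tbb"])$score
    expect_lt(abs(bt$levels$mean_score[1] - parent), 0.5)

    # marker proportion tracks the expected linear interpolation
    mkP <- markerProportion(reps[, "uip_tbb"], fixturePanel())
    mkD <- markerProportion(reps[, "blood"], fixturePanel())
    exp22 <- 0.78 * mkP + 0.22 * mkD
    got <- approx(bt$levels$fraction, bt$levels$marker_proportion,
                  xout = 0.22)$y
    expect_lt(abs(got - exp22), 0.01)
    expect_lt(abs(got - 0.07), 0.015)
})

test_that("gDNA spiking uses the stated design and a confound-free null", {
    reps <- fixtureRepCounts()
    model <- fixtureModel()
    g <- gdnaSpikeTest(reps[, c("uip_tbb", "nonuip_tbb", "nonuip_slb")],
                       fixtureProfiles()$gdna, model, fraction = 0.30,
                       nReplicates = 3, depth = 2e4, seed = 17)
    expect_identical(nrow(g$scores), 18L)  # 3 samples x 2 arms x triplicate
    expect_identical(g$levels, c(0, 0.30))

    # zero fraction: the two arms are exchangeable
    g0 <- gdnaSpikeTest(reps[, c("uip_tbb", "nonuip_tbb")],
                        fixtureProfiles()$gdna, model, fraction = 0,
                        nReplicates = 4, depth = 2e4, seed = 19)
    expect_lt(abs(g0$effect), 0.5)

    # gDNA profile identical to the sample: spiking changes no proportions
    self <- reps[, "uip_tbb"] / sum(reps[, "uip_tbb"])
    gd <- new("ExpressionProfile", name = "gdna", abundance = self,
              dispersion = 0)
    gs <- gdnaSpikeTest(reps[, "uip_tbb", drop = FALSE], gd, model,
                        fraction = 0.30, nReplicates = 6, depth = 2e4,
                        seed = 23)
    expect_false(gs$significant)
    expect_lt(abs(gs$effect), 0.5)

    expect_error(gdnaSpikeTest(reps[, 1:2], fixtureProfiles()$gdna, model,
                               nReplicates = 1), "replicates")
})

test_that("input-mass robustness: noisier scores at low mass, no trend", {
    cfg <- fixtureConfig()
    model <- fixtureModel()
    pr <- fixtureProfiles()[c("uip_tbb", "nonuip_tbb", "nonuip_slb")]
    r <- inputMassTest(pr, model, cfg, masses = c(5, 10, 15, 20, 30),
                       nReplicates = 8, seed = 29)
    expect_identical(nrow(r$scores), 3L * 5L * 8L)
    sd5 <- r$per_mass$sd_score[r$per_mass$mass == 5]
    sd30 <- r$per_mass$sd_score[r$per_mass$mass == 30]
    expect_gte(sd5, sd30)
})

test_that("blood and adjacent-normal materials never call UIP", {
    cfg <- fixtureConfig()
    pr <- fixtureProfiles()
    model <- fixtureModel()
    for (s in 1:10) {
        for (role in c("blood", "adjacent_normal", "nonuip_slb")) {
            k <- simulateCounts(pr[[role]], cfg, seed = 1000 + 10 * s +
                                    match(role, names(pr)))
            expect_identical(scoreCounts(model, k)$call, "non-UIP")
        }
    }
})
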