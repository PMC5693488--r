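test_that("mixture proportions follow exact linear mass mixing", {
    reps <- fixtureRepCounts()
    pp <- reps[, "uip_tbb"] / sum(reps[, "uip_tbb"])
    pd <- reps[, "blood"] / sum(reps[, "blood"])
    expect_equal(mixProportions(reps[, "uip_tbb"], reps[, "blood"], 0),
                 pp, tolerance = 1e-12)
    expect_equal(mixProportions(reps[, "uip_tbb"], reps[, "blood"], 1),
                 pd, tolerance = 1e-12)

    # proportion conservation across the whole fraction range
    for (f in seq(0, 1, 0.1))
        expect_lt(abs(sum(mixProportions(reps[, "uip_tbb"],
                                         reps[, "blood"], f)) - 1), 1e-9)

    # marker arithmetic: 0.3% baseline + 22% blood at 30.75% => 7%
    parent <- c(marker = 3, rest = 997)
    blood <- c(marker = 307.5, rest = 692.5)
    m <- mixProportions(parent, blood, 0.22)[["marker"]]
    expect_equal(m, 0.22 * 0.3075 + 0.78 * 0.003, tolerance = 1e-12)
    expect_lt(abs(m - 0.07), 2e-4)

    expect_error(mixProportions(c(0, 0), c(1, 1), 0.5), "all-zero")
})

test_that("mixture ensembles are seeded, calibrated and converge by LLN", {
    reps <- fixtureRepCounts()
    sp <- mixtureSpec("uip_tbb", "blood", 0.5, fractionJitterSD = 0.02,
                      depth = 2e4, nSimulations = 50, seed = 9)
    e1 <- simulateMixture(sp, reps)
    e2 <- simulateMixture(sp, reps)
    expect_identical(e1, e2)

    # sigma_f = 0, large depth: empirical proportions approach the target
    sp0 <- mixtureSpec("uip_tbb", "blood", 0.3, fractionJitterSD = 0,
                       depth = 2e6, nSimulations = 3, seed = 2)
    e0 <- simulateMixture(sp0, reps)
    target <- mixProportions(reps[, "uip_tbb"], reps[, "blood"], 0.3)
    emp <- rowMeans(sweep(e0$counts, 2, colSums(e0$counts), "/"))
    expect_lt(max(abs(emp - target)), 1e-3)

    # realized fractions are centered on the nominal fraction
    spf <- mixtureSpec("uip_tbb", "blood", 0.5, fractionJitterSD = 0.02,
                       depth = 1e3, nSimulations = 1000, seed = 4)
    ef <- simulateMixture(spf, reps)
    expect_lt(abs(mean(ef$fraction) - 0.5), 0.005)
})

test_that("replicate pairs are used in all possible combinations", {
    reps <- fixtureRepCounts()
    cn <- c("uip_tbb", "uip_slb", "blood", "adjacent_normal", "gdna")
    sub <- reps[, cn]
    sp <- mixtureSpec("uip_tbb", "blood", 0.4, depth = 1e3,
                      nSimulations = 12, seed = 1)
    e <- simulateMixture(sp, sub, parentCols = c("uip_tbb", "uip_slb"),
                         diluentCols = c("blood", "adjacent_normal",
                                         "gdna"))
    tab <- table(e$pair$parent, e$pair$diluent)
    expect_identical(dim(tab), c(2L, 3L))
    expect_true(all(tab == 2))
})

test_that("mean mixture score is monotone in the diluent fraction", {
    reps <- fixtureRepCounts()
    model <- fixtureModel()
    fr <- seq(0, 1, 0.05)
    ens <- simulateMixtureGrid(reps, "uip_tbb", "nonuip_slb", fr,
                               depth = 2e4, nSimulations = 60, seed = 21)
    means <- vapply(ens, function(e)
        mean(scoreCounts(model, e$counts)$score), numeric(1))
    expect_gt(means[[1]], 0)
    expect_lt(means[[length(means)]], 0)
    expect_true(all(diff(means) < 0.05))
    expect_lt(cor(fr, means), -0.99)
})
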