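test_that("panels have unique genes, one marker, and are seed-reproducible", {
    p <- makePanel(190, seed = 1)
    expect_length(geneIds(p), 190)
    expect_false(anyDuplicated(geneIds(p)) > 0)
    expect_true(markerGene(p) %in% geneIds(p))
    expect_true(all(exonicLength(p) > 0))

    expect_s4_class(makePanel(2, seed = 1), "GenePanel")
    expect_error(makePanel(1, seed = 1), "nGenes")

    expect_identical(makePanel(50, seed = 7), makePanel(50, seed = 7))
})

test_that("profiles sit on the simplex and carry the configured signature", {
    cfg <- fixtureConfig()
    pr <- fixtureProfiles()
    for (p in pr) expect_lt(abs(sum(abundance(p)) - 1), 1e-9)

    # classes differ on exactly nDiscriminating genes, by the exact logFC
    d <- abs(log(abundance(pr$uip_tbb)) - log(abundance(pr$nonuip_tbb)))
    expect_identical(sum(d > 1e-12), as.integer(cfg@nDiscriminating))
    expect_equal(unname(d[d > 1e-12]),
                 rep(cfg@logFoldChange, cfg@nDiscriminating),
                 tolerance = 1e-9)

    # zero class separation collapses the two classes
    cfg0 <- generatorConfig(nGenes = 40, nDiscriminating = 0, seed = 4)
    pr0 <- makeProfiles(makePanel(40, seed = 4), cfg0)
    expect_identical(abundance(pr0$uip_tbb), abundance(pr0$nonuip_tbb))

    # marker anchors
    mk <- markerGene(fixturePanel())
    expect_equal(unname(abundance(pr$blood)[mk]),
                 cfg@pureBloodMarkerFraction, tolerance = 1e-12)
    expect_equal(unname(abundance(pr$uip_tbb)[mk]),
                 cfg@baselineMarkerFraction, tolerance = 1e-12)

    # gDNA abundance proportional to exonic length
    len <- exonicLength(fixturePanel())
    ratio <- abundance(pr$gdna) / (len / sum(len))
    expect_equal(unname(ratio), rep(1, length(ratio)), tolerance = 1e-12)

    expect_error(generatorConfig(nGenes = 10, nDiscriminating = 10),
                 "nDiscriminating")
})

test_that("counts are seeded NB draws with the stated mean-variance law", {
    cfg <- fixtureConfig()
    pr <- fixtureProfiles()
    expect_identical(simulateCounts(pr$uip_tbb, cfg, seed = 42),
                     simulateCounts(pr$uip_tbb, cfg, seed = 42))

    # Poisson / LLN limit: proportions converge to abundance
    p0 <- new("ExpressionProfile", name = "x",
              abundance = abundance(pr$uip_tbb), dispersion = 0)
    cfgBig <- generatorConfig(nGenes = cfg@nGenes, depth = 5e6,
                              massJitterSD = 0, seed = 11)
    k <- simulateCounts(p0, cfgBig, seed = 1)
    expect_lt(max(abs(k / sum(k) - abundance(p0))), 5e-4)

    # moment check: var ~= mu * (1 + alpha * mu) at alpha = 0.05
    alpha <- 0.05
    ab <- rep(1 / 50, 50); names(ab) <- sprintf("g%02d", 1:50)
    pm <- new("ExpressionProfile", name = "m", abundance = ab,
              dispersion = alpha)
    cfgM <- generatorConfig(nGenes = 50, depth = 1e5, massJitterSD = 0,
                            seed = 1)
    reps <- vapply(1:500, function(i) simulateCounts(pm, cfgM, seed = i),
                   integer(50))
    mu <- rowMeans(reps)
    vr <- apply(reps, 1, var)
    expect_equal(mean(vr / (mu * (1 + alpha * mu))), 1, tolerance = 0.1)
})

test_that("pure-blood libraries reproduce the configured marker fraction", {
    cfg <- generatorConfig(nGenes = 80, depth = 1e5, seed = 11)
    pr <- makeProfiles(makePanel(80, seed = 11), cfg)
    props <- vapply(1:20, function(s)
        markerProportion(simulateCounts(pr$blood, cfg, seed = s),
                         makePanel(80, seed = 11)),
        numeric(1))
    expect_true(all(abs(props - cfg@pureBloodMarkerFraction) < 0.02))
})

test_that("study simulation emits the full factorial design with truth", {
    cfg <- generatorConfig(nGenes = 30, nDiscriminating = 4, depth = 5e3,
                           seed = 9)
    lay <- studyLayout(9, 3, 1, 3)
    expect_identical(nrow(lay), 81L)
    se <- simulateStudy(lay, cfg, seed = 2)
    expect_identical(dim(se), c(30L, 81L))
    truth <- S4Vectors::metadata(se)$truth
    expect_length(truth$residual, 81)

    # degenerate noise: zero run/lab/residual SDs leave only the subject
    # effect, constant across a subject's replicates
    cfg0 <- generatorConfig(nGenes = 30, nDiscriminating = 4, depth = 5e3,
                            runEffectSD = 0, labEffectSD = 0,
                            residualSD = 0, seed = 9)
    se0 <- simulateStudy(studyLayout(3, 2, 1, 2), cfg0, seed = 5)
    tr0 <- S4Vectors::metadata(se0)$truth
    shift <- unlist(tr0$total_shift)
    subj <- SummarizedExperiment::colData(se0)$subject_id
    expect_true(all(tapply(shift, subj, function(x) diff(range(x))) == 0))

    expect_error(simulateStudy(lay[0, ], cfg, seed = 1), "nonempty")
})

test_that("truth records and TSV outputs round-trip identically", {
    cfg <- generatorConfig(nGenes = 25, nDiscriminating = 4, depth = 4e3,
                           seed = 3)
    se <- simulateStudy(studyLayout(2, 2, 1, 2), cfg, seed = 8)
    truth <- S4Vectors::metadata(se)$truth

    tf <- tempfile(fileext = ".json")
    writeTruthRecord(truth, tf)
    expect_identical(readTruthRecord(tf), truth)

    # identical (config, seed) => identical emitted bytes
    f1 <- tempfile(); f2 <- tempfile()
    writeCounts(se, f1)
    writeCounts(simulateStudy(studyLayout(2, 2, 1, 2), cfg, seed = 8), f2)
    expect_identical(readLines(f1), readLines(f2))

    m <- readCounts(f1)
    expect_identical(m, SummarizedExperiment::assay(se, "counts"))

    ann <- as.data.frame(SummarizedExperiment::colData(se))
    fa <- tempfile()
    writeAnnotations(ann, fa)
    back <- readAnnotations(fa)
    expect_identical(back$sample_id, ann$sample_id)
    expect_equal(back$dv200, ann$dv200, tolerance = 1e-9)

    fc <- tempfile(fileext = ".json")
    writeGeneratorConfig(cfg, fc)
    expect_identical(readGeneratorConfig(fc), cfg)
})
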