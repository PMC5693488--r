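test_that("training separates the synthetic classes and is deterministic", {
    tr <- fixtureTraining()
    model <- fixtureModel()
    sc <- scoreCounts(model, tr$counts)
    expect_identical(sc$call, ifelse(tr$labels == "UIP", "UIP", "non-UIP"))

    m2 <- trainFromCounts(tr$counts, tr$labels, seed = 11L)
    expect_identical(modelWeights(m2), modelWeights(model))

    expect_error(trainFromCounts(tr$counts, rep("UIP", ncol(tr$counts))),
                 "both classes")

    # class-mean profiles land on the right sides of the boundary
    pr <- fixtureProfiles()
    cfg <- fixtureConfig()
    mean_counts <- function(p)
        setNames(as.integer(round(cfg@depth * abundance(p))),
                 names(abundance(p)))
    expect_gt(scoreCounts(model, mean_counts(pr$uip_tbb))$score, 0)
    expect_lt(scoreCounts(model, mean_counts(pr$nonuip_tbb))$score, 0)
})

test_that("scoring is pure, locked, affine, and ties call non-UIP", {
    model <- fixtureModel()
    tr <- fixtureTraining()
    sf <- estimateSizeFactors(tr$counts)
    vst <- vstTransform(tr$counts, sf, model@dispersion)

    # lockedness: any batch split or order gives identical scores
    all_at_once <- scoreSample(model, vst)$score
    one_by_one <- vapply(seq_len(ncol(vst)), function(j)
        scoreSample(model, vst[, j])$score, numeric(1))
    expect_identical(all_at_once, one_by_one)
    shuffled <- scoreSample(model, vst[, c(5, 1, 3)])$score
    expect_identical(shuffled, all_at_once[c(5, 1, 3)])

    # purity
    expect_identical(scoreSample(model, vst[, 1]),
                     scoreSample(model, vst[, 1]))

    # score is affine: convex combinations commute with scoring
    lam <- 0.3
    combo <- lam * vst[, 1] + (1 - lam) * vst[, 2]
    expect_equal(scoreSample(model, combo)$score,
                 lam * all_at_once[1] + (1 - lam) * all_at_once[2],
                 tolerance = 1e-10)

    # a score exactly at the boundary calls non-UIP
    tie <- new("ClassifierModel",
               weights = c(g1 = 1, g2 = -1), intercept = 0, scale = 1,
               boundary = 0, refLogMeans = c(g1 = NA_real_, g2 = NA_real_),
               dispersion = 0, metadata = list())
    hit <- scoreSample(tie, c(g1 = 2, g2 = 2))
    expect_identical(hit$score, 0)
    expect_identical(hit$call, "non-UIP")

    expect_error(scoreSample(model, vst[-1, 1]), "length")
})

test_that("models survive JSON serialization without score drift", {
    model <- fixtureModel()
    reps <- fixtureRepCounts()
    path <- tempfile(fileext = ".json")
    writeClassifierModel(model, path)
    back <- readClassifierModel(path)
    expect_identical(scoreCounts(back, reps), scoreCounts(model, reps))
})

test_that("cross-validation is stratified, seeded, and calibrated", {
    tr <- fixtureTraining()
    sf <- estimateSizeFactors(tr$counts)
    alpha <- estimateDispersion(tr$counts, sf)
    vst <- vstTransform(tr$counts, sf, alpha)

    cv <- evaluateCV(vst, tr$labels, folds = 5, seed = 3)
    expect_identical(cv$sensitivity, 1)
    expect_identical(cv$specificity, 1)
    expect_identical(evaluateCV(vst, tr$labels, folds = 5, seed = 3)$scores,
                     cv$scores)
    expect_error(evaluateCV(vst, tr$labels, folds = 50, seed = 1), "folds")

    # permutation null: accuracy collapses to chance
    set.seed(77)
    accs <- vapply(1:5, function(i) {
        perm <- sample(tr$labels)
        cvp <- evaluateCV(vst, perm, folds = 5, seed = i)
        (cvp$sensitivity + cvp$specificity) / 2
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.5), 0.2)
})
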