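# Shared fixtures, built once per test run and cached. Sizes are kept small
# (80-gene panel, 4e4 reads) so the whole suite stays fast; the generative
# structure is identical to the full-size defaults.

.fixtures <- new.env(parent = emptyenv())

fixtureConfig <- function() {
    if (is.null(.fixtures$config))
        .fixtures$config <- generatorConfig(
            nGenes = 80L, nDiscriminating = 10L, logFoldChange = 1.0,
            depth = 4e4, seed = 11L)
    .fixtures$config
}

fixturePanel <- function() {
    if (is.null(.fixtures$panel))
        .fixtures$panel <- makePanel(fixtureConfig()@nGenes, seed = 11L)
    .fixtures$panel
}

fixtureProfiles <- function() {
    if (is.null(.fixtures$profiles))
        .fixtures$profiles <- makeProfiles(fixturePanel(), fixtureConfig())
    .fixtures$profiles
}

# Training cohort: per-subject biological tilts along the class axis, then
# NB counts; mirrors the validation suite's training stage.
fixtureTraining <- function() {
    if (is.null(.fixtures$train)) {
        cfg <- fixtureConfig()
        pr <- fixtureProfiles()
        labels <- rep(c("UIP", "non-UIP"), each = 10L)
        axis <- log(abundance(pr$uip_tbb)) - log(abundance(pr$nonuip_tbb))
        set.seed(101)
        shifts <- rnorm(length(labels), 0, 0.5)
        m <- vapply(seq_along(labels), function(i) {
            p <- pr[[if (labels[i] == "UIP") "uip_tbb" else "nonuip_tbb"]]
            ab <- abundance(p) * exp((shifts[i] / cfg@classScoreGap) * axis)
            ab <- ab / sum(ab)
            tp <- new("ExpressionProfile", name = p@name, abundance = ab,
                      dispersion = p@dispersion)
            simulateCounts(tp, cfg, seed = 500L + i)
        }, integer(cfg@nGenes))
        rownames(m) <- geneIds(fixturePanel())
        colnames(m) <- sprintf("tr%02d", seq_along(labels))
        .fixtures$train <- list(counts = m, labels = labels)
    }
    .fixtures$train
}

fixtureModel <- function() {
    if (is.null(.fixtures$model)) {
        tr <- fixtureTraining()
        .fixtures$model <- trainFromCounts(tr$counts, tr$labels,
                                           seed = 11L)
    }
    .fixtures$model
}

# One representative library per material role.
fixtureRepCounts <- function() {
    if (is.null(.fixtures$reps)) {
        cfg <- fixtureConfig()
        pr <- fixtureProfiles()
        m <- vapply(seq_along(pr), function(i)
            simulateCounts(pr[[i]], cfg, seed = 900L + i),
            integer(cfg@nGenes))
        colnames(m) <- names(pr)
        rownames(m) <- geneIds(fixturePanel())
        .fixtures$reps <- m
    }
    .fixtures$reps
}

# Score table for a balanced reproducibility design with known injected
# variances: per-sample means + N(0, runVar) run effects + N(0, residVar)
# residuals. Used wherever closed-form component recovery is checked.
simulateScoreTable <- function(nSamples = 9, nRuns = 3, nReps = 3,
                               runVar = 0.0076, residVar = 0.0324,
                               sampleMeans = NULL, seed = 1) {
    set.seed(seed)
    if (is.null(sampleMeans))
        sampleMeans <- seq(-3, 3, length.out = nSamples)
    g <- expand.grid(rep = seq_len(nReps), run = seq_len(nRuns),
                     sample = seq_len(nSamples))
    runEff <- rnorm(nSamples * nRuns, 0, sqrt(runVar))
    cellIdx <- (g$sample - 1) * nRuns + g$run
    data.frame(
        sample_id = sprintf("S%02d", g$sample),
        run_id = sprintf("R%d", g$run),
        class_label = ifelse(g$sample %% 2 == 1, "UIP", "non-UIP"),
        score = sampleMeans[g$sample] + runEff[cellIdx] +
            rnorm(nrow(g), 0, sqrt(residVar)))
}
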