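#' Run the full analytical-verification suite
#'
#' Orchestrates the verification battery end to end on synthetic data:
#' simulate a training cohort, normalize/transform and train the surrogate
#' locked classifier, check classifier quality in cross validation, then
#' run three limit-of-detection titrations (UIP-SLB diluent into a non-UIP
#' parent; blood and adjacent-normal diluents into a UIP parent), the
#' genomic-DNA and input-mass interference tests, the replicated
#' reproducibility study with variance components and bootstrap CIs, the
#' two-laboratory comparison, the noise-tolerance simulation, and the
#' storage-stability ANOVA. A single top-level seed fans out to per-stage
#' child seeds through a fixed deterministic derivation, so the report
#' regenerates bit-for-bit from (config, seed).
#'
#' If cross-validated sensitivity or specificity falls below
#' \code{minCvPerformance} the suite flags a classifier-quality failure
#' and skips the stages that depend on a usable classifier.
#'
#' @param config a \code{GeneratorConfig}.
#' @param seed top-level seed.
#' @param outDir optional directory; when given, \code{report.json} and
#'   \code{report.md} are written there.
#' @param nTrainPerClass training samples per class.
#' @param lodFractions diluent-fraction grid for LOD titrations.
#' @param nSimPerFraction simulated mixtures per grid point.
#' @param nBootstrap bootstrap replicates for CIs.
#' @param mixDepth reads per simulated mixture.
#' @param minCvPerformance quality gate on CV sensitivity and specificity.
#' @return the validation report as a nested list (invisibly when written
#'   to disk).
#' @export
runValidationSuite <- function(config = generatorConfig(),
                               seed = 1L,
                               outDir = NULL,
                               nTrainPerClass = 20L,
                               lodFractions = seq(0, 1, by = 0.05),
                               nSimPerFraction = 100L,
                               nBootstrap = 200L,
                               mixDepth = 5e4,
                               minCvPerformance = 0.8) {
    stopIfNot(is(config, "GeneratorConfig"),
              "config must be a GeneratorConfig")
    seed <- as.integer(seed)
    panel <- makePanel(config@nGenes, seed = config@seed)
    profiles <- makeProfiles(panel, config)
    axis <- classAxis(profiles)

    # -- stage 1: training cohort ------------------------------------------
    sTrain <- childSeed(seed, 1)
    labels <- rep(c("UIP", "non-UIP"), each = nTrainPerClass)
    train <- withSeed(sTrain, {
        shifts <- rnorm(2 * nTrainPerClass, 0, 0.5)
        m <- vapply(seq_along(labels), function(i) {
            p <- profiles[[if (labels[i] == "UIP") "uip_tbb"
                           else "nonuip_tbb"]]
            ab <- tiltAbundance(abundance(p), axis, shifts[i],
                                config@classScoreGap)
            tp <- new("ExpressionProfile", name = p@name, abundance = ab,
                      dispersion = p@dispersion)
            simulateCounts(tp, config, seed = childSeed(sTrain, i))
        }, integer(config@nGenes))
        colnames(m) <- sprintf("train_%02d", seq_along(labels))
        rownames(m) <- geneIds(panel)
        m
    })
    model <- trainFromCounts(train, labels, seed = sTrain)

    sf <- estimateSizeFactors(train)
    vst <- vstTransform(train, sf, model@dispersion)
    cv <- evaluateCV(vst, labels, folds = 5L, seed = childSeed(seed, 2))
    classifierOk <- cv$sensitivity >= minCvPerformance &&
        cv$specificity >= minCvPerformance

    report <- list(
        seed = seed,
        config = configDigest(config),
        classifier = list(
            cv_sensitivity = cv$sensitivity,
            cv_specificity = cv$specificity,
            n_train = length(labels)),
        flags = list(classifier_quality = classifierOk))

    if (!classifierOk) {
        report$flags$aborted_before_lod <- TRUE
        return(finishReport(report, outDir))
    }

    # -- stage 2: representative parent/diluent libraries ------------------
    sRep <- childSeed(seed, 3)
    reps <- vapply(names(profiles), function(r)
        simulateCounts(profiles[[r]], config,
                       seed = childSeed(sRep, match(r, names(profiles)))),
        integer(config@nGenes))
    rownames(reps) <- geneIds(panel)

    # -- stage 3: limit-of-detection titrations ----------------------------
    lodStudy <- function(parent, diluent, k) {
        ens <- simulateMixtureGrid(reps, parent, diluent, lodFractions,
                                   fractionJitterSD =
                                       config@fractionJitterSD,
                                   depth = mixDepth,
                                   nSimulations = nSimPerFraction,
                                   seed = childSeed(seed, 10 + k))
        ref <- scoreCounts(model, reps[, parent])$call
        res <- lodFromEnsembles(ens, model, ref, nBootstrap = nBootstrap,
                                seed = childSeed(seed, 20 + k))
        list(parent = parent, diluent = diluent, reference_call = ref,
             lod = lodAsList(res$lod), curve = res$curve)
    }
    blood <- bloodTitration(reps, "uip_tbb", "blood", lodFractions, model,
                            panel,
                            fractionJitterSD = config@fractionJitterSD,
                            depth = mixDepth,
                            nSimulations = nSimPerFraction,
                            nBootstrap = nBootstrap,
                            seed = childSeed(seed, 12))
    report$lod_studies <- list(
        uip_diluent = lodStudy("nonuip_tbb", "uip_slb", 1),
        blood_diluent = list(parent = "uip_tbb", diluent = "blood",
                             reference_call = blood$reference_call,
                             lod = lodAsList(blood$lod),
                             curve = blood$curve),
        adjacent_normal_diluent = lodStudy("uip_tbb", "adjacent_normal", 3))

    # -- stage 4: interference ---------------------------------------------
    gdna <- gdnaSpikeTest(reps[, c("uip_tbb", "nonuip_tbb", "nonuip_slb")],
                          profiles$gdna, model, fraction = 0.30,
                          nReplicates = 3L, depth = mixDepth,
                          seed = childSeed(seed, 30))
    mass <- inputMassTest(profiles[c("uip_tbb", "nonuip_tbb",
                                     "nonuip_slb")],
                          model, config, nReplicates = 3L,
                          seed = childSeed(seed, 31))
    report$interference <- list(
        blood = list(levels = blood$levels,
                     tolerance_fraction = lodValue(blood$lod)),
        gdna = list(effect = gdna$effect, p_value = gdna$p_value,
                    significant = gdna$significant),
        input_mass = list(per_mass = mass$per_mass, effect = mass$effect,
                          p_value = mass$p_value,
                          significant = mass$significant))

    # -- stage 5: reproducibility ------------------------------------------
    se <- simulateStudy(studyLayout(9L, 3L, 1L, 3L), config,
                        seed = childSeed(seed, 40),
                        profiles = profiles, panel = panel, model = model)
    sc <- scoreCounts(model, SummarizedExperiment::assay(se, "counts"))
    repro <- cbind(sc, as.data.frame(SummarizedExperiment::colData(se))[
        , c("subject_id", "class_label", "lab_id", "run_id",
            "replicate_index")])
    repro$sample_id <- repro$subject_id
    vc <- estimateVarianceComponents(repro)
    ciW <- sdBootstrapCi(repro, "within_run", nBootstrap = nBootstrap,
                         seed = childSeed(seed, 41))
    ciR <- sdBootstrapCi(repro, "run_to_run", nBootstrap = nBootstrap,
                         seed = childSeed(seed, 42))

    se2 <- simulateStudy(studyLayout(20L, 1L, 2L, 1L), config,
                         seed = childSeed(seed, 43),
                         profiles = profiles, panel = panel,
                         model = model)
    sc2 <- scoreCounts(model, SummarizedExperiment::assay(se2, "counts"))
    cd2 <- as.data.frame(SummarizedExperiment::colData(se2))
    byLab <- split(data.frame(score = sc2$score,
                              subject = cd2$subject_id), cd2$lab_id)
    ordA <- order(byLab[[1]]$subject); ordB <- order(byLab[[2]]$subject)
    il <- interlabConcordance(byLab[[1]]$score[ordA],
                              byLab[[2]]$score[ordB])

    tol <- noiseTolerance(vst, labels, seed = childSeed(seed, 44))

    sStab <- childSeed(seed, 45)
    stab <- withSeed(sStab, {
        bins <- rep(c("0-3d", "4-7d", "8-14d"), each = 30)
        storageAnova(rnorm(length(bins), 70, 5), bins)
    })

    report$reproducibility <- list(
        variance_components = list(
            within_run_sd = vc@withinRunSD, within_run_ci = unname(ciW),
            run_to_run_sd = vc@runToRunSD, run_to_run_ci = unname(ciR),
            interclass_sd = vc@interclassSD),
        interlab = il[c("concordancePct", "r2", "pooledSD", "n")],
        noise_tolerance = list(max_tolerable_sd = tol$maxTolerableSD,
                               baseline = as.list(tol$baseline),
                               margin = tol$margin,
                               grid = tol$grid),
        storage = list(F = stab$F, p_value = stab$p_value))

    report$flags <- c(report$flags, list(
        lod_estimated = all(vapply(report$lod_studies,
                                   function(x) x$lod$estimate > 0,
                                   logical(1))),
        gdna_no_effect = !gdna$significant,
        input_mass_no_effect = !mass$significant,
        interlab_concordant = il$concordancePct == 100,
        storage_stable = stab$p_value >= 0.05,
        noise_tolerance_ok = tol$maxTolerableSD >= 0.48))

    finishReport(report, outDir)
}

lodAsList <- function(lod) {
    list(estimate = lod@estimate, lower = lod@lower, upper = lod@upper,
         threshold = lod@threshold, method = lod@method, flag = lod@flag)
}

configDigest <- function(config) {
    sl <- slotNames(config)
    v <- lapply(sl, function(s) slot(config, s))
    names(v) <- sl
    v
}

finishReport <- function(report, outDir) {
    if (is.null(outDir)) return(report)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                         dataframe = "columns")
    writeLines(reportMarkdown(report), file.path(outDir, "report.md"))
    invisible(report)
}

reportMarkdown <- function(report) {
    out <- c("# Analytical verification report", "",
             sprintf("seed: %d", report$seed), "",
             "## Classifier",
             sprintf("- CV sensitivity: %.3f",
                     report$classifier$cv_sensitivity),
             sprintf("- CV specificity: %.3f",
                     report$classifier$cv_specificity))
    if (!is.null(report$lod_studies)) {
        out <- c(out, "", "## Limits of detection")
        for (nm in names(report$lod_studies)) {
            st <- report$lod_studies[[nm]]
            out <- c(out, sprintf(
                "- %s (%s + %s): f = %.3f [%.3f, %.3f] (%s)", nm,
                st$parent, st$diluent, st$lod$estimate, st$lod$lower,
                st$lod$upper, st$lod$flag))
        }
    }
    if (!is.null(report$interference)) {
        out <- c(out, "", "## Interference",
                 sprintf("- gDNA spike: effect %.4f, p = %.3g",
                         report$interference$gdna$effect,
                         report$interference$gdna$p_value),
                 sprintf("- input mass: effect %.4g /ng, p = %.3g",
                         report$interference$input_mass$effect,
                         report$interference$input_mass$p_value))
    }
    if (!is.null(report$reproducibility)) {
        vcr <- report$reproducibility$variance_components
        out <- c(out, "", "## Reproducibility",
                 "| component | SD | 95% CI |", "|---|---|---|",
                 sprintf("| within-run | %.3f | [%.3f, %.3f] |",
                         vcr$within_run_sd, vcr$within_run_ci[1],
                         vcr$within_run_ci[2]),
                 sprintf("| run-to-run | %.3f | [%.3f, %.3f] |",
                         vcr$run_to_run_sd, vcr$run_to_run_ci[1],
                         vcr$run_to_run_ci[2]),
                 sprintf("| inter-lab | %.3f | (pooled, %d samples) |",
                         report$reproducibility$interlab$pooledSD,
                         report$reproducibility$interlab$n),
                 sprintf("| inter-class | %.3f | |", vcr$interclass_sd),
                 "",
                 sprintf("- inter-lab concordance: %.1f%% (R2 = %.3f)",
                         report$reproducibility$interlab$concordancePct,
                         report$reproducibility$interlab$r2),
                 sprintf("- max tolerable score SD: %.2f",
                         report$reproducibility$noise_tolerance$max_tolerable_sd),
                 sprintf("- storage ANOVA: p = %.3g",
                         report$reproducibility$storage$p_value))
    }
    out <- c(out, "", "## Flags")
    for (nm in names(report$flags))
        out <- c(out, sprintf("- %s: %s", nm,
                              ifelse(isTRUE(report$flags[[nm]]), "PASS",
                                     "FAIL")))
    out
}
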