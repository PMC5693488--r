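#' Construct a generator configuration
#'
#' Builds a validated \code{\linkS4class{GeneratorConfig}} holding every
#' tunable of the synthetic study generator. Defaults encode the nominal
#' assay conditions: a 190-gene panel read to an expected depth of 1e6
#' counts from 15 ng of input RNA, negative-binomial dispersion 0.05,
#' run-effect variance 0.0076 and replicate-residual variance 0.0324 on the
#' score scale, mixing-fraction jitter SD 0.02, a pure-blood marker-gene
#' fraction of 0.3075 and a baseline tissue marker fraction of 0.003.
#'
#' @param nGenes panel size.
#' @param nDiscriminating even count of class-discriminating genes.
#' @param logFoldChange natural-log fold change on each discriminating gene.
#' @param depth expected total counts per sample at nominal mass.
#' @param dispersion NB dispersion alpha of tissue profiles.
#' @param bloodDispersion NB dispersion of the pooled whole-blood profile.
#' @param technicalDispersion NB dispersion of technical replicate
#'   libraries drawn from the same pooled RNA (library-level
#'   overdispersion only; between-subject biology is carried by
#'   \code{dispersion}).
#' @param runEffectSD,labEffectSD,residualSD score-scale technical SDs.
#' @param fractionJitterSD SD of mixture mass-fraction jitter.
#' @param pureBloodMarkerFraction marker abundance of pure blood.
#' @param baselineMarkerFraction marker abundance of tissue profiles.
#' @param massRefNg nominal RNA input mass in ng.
#' @param massDepthExponent exponent of mass-to-effective-depth scaling
#'   (0 = input mass has no effect; the null generator).
#' @param massJitterSD lognormal depth jitter SD at the reference mass.
#' @param classScoreGap score units separating the class profiles; used to
#'   convert score-scale effects into count-level tilts.
#' @param seed base seed fixing all downstream randomness.
#' @return a \code{GeneratorConfig}.
#' @examples
#' cfg <- generatorConfig(nGenes = 50, depth = 1e4)
#' cfg
#' @export
generatorConfig <- function(nGenes = 190L,
                            nDiscriminating = 20L,
                            logFoldChange = 1.0,
                            depth = 1e6,
                            dispersion = 0.05,
                            bloodDispersion = 0.001,
                            technicalDispersion = 0.002,
                            runEffectSD = sqrt(0.0076),
                            labEffectSD = 0.10,
                            residualSD = sqrt(0.0324),
                            fractionJitterSD = 0.02,
                            pureBloodMarkerFraction = 0.3075,
                            baselineMarkerFraction = 0.003,
                            massRefNg = 15,
                            massDepthExponent = 1,
                            massJitterSD = 0.05,
                            classScoreGap = 2,
                            seed = 190L) {
    new("GeneratorConfig",
        nGenes = as.integer(nGenes),
        nDiscriminating = as.integer(nDiscriminating),
        logFoldChange = logFoldChange,
        depth = depth,
        dispersion = dispersion,
        bloodDispersion = bloodDispersion,
        technicalDispersion = technicalDispersion,
        runEffectSD = runEffectSD,
        labEffectSD = labEffectSD,
        residualSD = residualSD,
        fractionJitterSD = fractionJitterSD,
        pureBloodMarkerFraction = pureBloodMarkerFraction,
        baselineMarkerFraction = baselineMarkerFraction,
        massRefNg = massRefNg,
        massDepthExponent = massDepthExponent,
        massJitterSD = massJitterSD,
        classScoreGap = classScoreGap,
        seed = as.integer(seed))
}

#' Generate a synthetic gene panel
#'
#' Creates a \code{\linkS4class{GenePanel}} with synthetic gene identifiers
#' (\code{G0001}, ...), per-gene exonic lengths drawn from a lognormal
#' distribution (median 1500 bases, sdlog 0.6 - typical of exon-capture
#' panels), and a designated blood marker gene. Gene identities are
#' synthetic throughout: the framework is panel-agnostic and no real panel
#' content is reproduced.
#'
#' @param nGenes number of genes (>= 2); default 190.
#' @param seed RNG seed for the length draw.
#' @return a \code{GenePanel}.
#' @examples
#' makePanel(10, seed = 1)
#' @export
makePanel <- function(nGenes = 190L, seed = 1L) {
    stopIfNot(is.numeric(nGenes) && length(nGenes) == 1L && nGenes >= 2,
              "nGenes must be a single number >= 2")
    nGenes <- as.integer(nGenes)
    ids <- sprintf("G%04d", seq_len(nGenes))
    len <- withSeed(seed, round(rlnorm(nGenes, log(1500), 0.6)))
    len <- pmax(len, 100)
    new("GenePanel", geneIds = ids, markerGene = ids[1L],
        exonicLength = as.numeric(len))
}

# Roles a profile set always contains. Tissue roles carry the baseline
# marker fraction; blood carries the pure-blood fraction; gdna is
# length-proportional.
.profileRoles <- c("uip_tbb", "nonuip_tbb", "uip_slb", "nonuip_slb",
                   "blood", "adjacent_normal", "gdna")

#' Generate tissue, blood and gDNA expression profiles
#'
#' Builds one \code{\linkS4class{ExpressionProfile}} per material role:
#' UIP and non-UIP transbronchial-biopsy pools (\code{uip_tbb},
#' \code{nonuip_tbb}), UIP and non-UIP surgical-lung-biopsy profiles,
#' whole blood, adjacent normal lung tissue, and a genomic-DNA background.
#'
#' The two classes differ on exactly \code{nDiscriminating} genes: within
#' the discriminating block, half the genes are up and half down by the
#' configured log-fold change, with the block rescaled so its total mass is
#' preserved exactly - all other genes are bitwise identical between the
#' class profiles. SLB, blood and adjacent-normal profiles carry the
#' non-discriminating-gene perturbations of distinct source materials but
#' share a class signature: \code{uip_slb} the UIP pattern, all others the
#' non-UIP pattern (whole blood and normal tissues score non-UIP). The
#' blood profile's marker-gene abundance equals the configured pure-blood
#' marker fraction; tissue profiles carry the baseline fraction. The gDNA
#' profile allocates abundance proportional to exonic length, as an
#' exon-capture assay retains exonic gDNA fragments.
#'
#' @param panel a \code{GenePanel}.
#' @param config a \code{GeneratorConfig}; its \code{seed} fixes the draw.
#' @return named list of \code{ExpressionProfile}s (one per role).
#' @examples
#' cfg <- generatorConfig(nGenes = 30, nDiscriminating = 4)
#' pr <- makeProfiles(makePanel(30, seed = 1), cfg)
#' names(pr)
#' @export
makeProfiles <- function(panel, config) {
    stopIfNot(is(panel, "GenePanel"), "panel must be a GenePanel")
    stopIfNot(is(config, "GeneratorConfig"),
              "config must be a GeneratorConfig")
    ids <- geneIds(panel)
    nG <- length(ids)
    nD <- config@nDiscriminating
    stopIfNot(nD <= nG - 1L,
              "more discriminating genes than non-marker panel genes")
    marker <- markerGene(panel)

    withSeed(config@seed, {
        base <- rlnorm(nG, 0, 1.5)
        names(base) <- ids
        nonMarker <- setdiff(ids, marker)
        disc <- sample(nonMarker, nD)
        # equalize the discriminating block so the +/- logFC tilt preserves
        # its total mass exactly
        if (nD > 0) base[disc] <- median(base[disc])
        base[marker] <- 0
        base[nonMarker] <- base[nonMarker] / sum(base[nonMarker]) *
            (1 - config@baselineMarkerFraction)
        base[marker] <- config@baselineMarkerFraction

        up <- disc[seq_len(nD / 2)]
        down <- setdiff(disc, up)
        half <- config@logFoldChange / 2
        sig <- function(x, direction) {
            if (nD == 0) return(x)
            x[up] <- x[up] * exp(direction * half) / cosh(half)
            x[down] <- x[down] * exp(-direction * half) / cosh(half)
            x
        }
        tissueJitter <- function(x, sdlog) {
            # perturb only non-discriminating, non-marker genes, preserving
            # their block mass, so the class signature is untouched
            free <- setdiff(nonMarker, disc)
            j <- rlnorm(length(free), 0, sdlog)
            x[free] <- x[free] * j / sum(x[free] * j) * sum(x[free])
            x
        }

        uipTbb <- sig(base, +1)
        nonuipTbb <- sig(base, -1)
        uipSlb <- tissueJitter(sig(base, +1), 0.3)
        nonuipSlb <- tissueJitter(sig(base, -1), 0.3)
        adjNorm <- tissueJitter(sig(base, -1), 0.4)

        blood <- tissueJitter(sig(base, -1), 0.5)
        blood[marker] <- 0
        blood <- blood / sum(blood) * (1 - config@pureBloodMarkerFraction)
        blood[marker] <- config@pureBloodMarkerFraction

        gdna <- exonicLength(panel)
        gdna <- gdna / sum(gdna)

        mk <- function(name, ab, alpha)
            new("ExpressionProfile", name = name, abundance = ab,
                dispersion = alpha)
        a <- config@dispersion
        list(
            uip_tbb = mk("uip_tbb", uipTbb, a),
            nonuip_tbb = mk("nonuip_tbb", nonuipTbb, a),
            uip_slb = mk("uip_slb", uipSlb, a),
            nonuip_slb = mk("nonuip_slb", nonuipSlb, a),
            blood = mk("blood", blood, config@bloodDispersion),
            adjacent_normal = mk("adjacent_normal", adjNorm, a),
            gdna = mk("gdna", gdna, a)
        )
    })
}

# Discriminating-gene log-abundance axis (uip minus nonuip); used to convert
# score-scale effects into count-level tilts.
classAxis <- function(profiles) {
    log(abundance(profiles$uip_tbb)) - log(abundance(profiles$nonuip_tbb))
}

# Tilt a profile along the class axis by `shift` score units: moving
# classScoreGap units traverses the full uip vs nonuip log-abundance
# difference.
tiltAbundance <- function(ab, axis, shift, gap) {
    x <- ab * exp((shift / gap) * axis)
    x / sum(x)
}

#' Draw a negative-binomial count column for one sample
#'
#' Draws per-gene counts for a single library from an expression profile:
#' counts are negative-binomial (gamma-Poisson) with mean
#' \code{depth * abundance} and the profile's dispersion alpha, so that
#' variance = mu + alpha * mu^2. The effective depth scales with RNA input
#' mass as \code{(mass/massRefNg)^massDepthExponent} and carries a
#' mass-dependent lognormal jitter whose sdlog grows as
#' \code{sqrt(massRefNg/mass)}: lower input mass yields fewer effective
#' reads and noisier totals.
#'
#' @param profile an \code{ExpressionProfile}.
#' @param config a \code{GeneratorConfig}.
#' @param seed RNG seed.
#' @param inputMassNg RNA input mass in ng (default: the nominal mass).
#' @param depth expected total counts at nominal mass (default from config).
#' @return named integer vector of per-gene counts.
#' @examples
#' cfg <- generatorConfig(nGenes = 20, depth = 1e4)
#' pr <- makeProfiles(makePanel(20, seed = 1), cfg)
#' head(simulateCounts(pr$uip_tbb, cfg, seed = 7))
#' @export
simulateCounts <- function(profile, config, seed,
                           inputMassNg = config@massRefNg,
                           depth = config@depth) {
    stopIfNot(is(profile, "ExpressionProfile"),
              "profile must be an ExpressionProfile")
    stopIfNot(depth > 0, "depth must be positive")
    stopIfNot(inputMassNg > 0, "input mass must be positive")
    ab <- abundance(profile)
    alpha <- dispersion(profile)
    e <- config@massDepthExponent
    eff <- depth * (inputMassNg / config@massRefNg)^e
    sdlog <- config@massJitterSD * (config@massRefNg / inputMassNg)^(e / 2)
    withSeed(seed, {
        f <- if (sdlog > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1
        mu <- eff * f * ab
        k <- if (alpha > 0) rnbinom(length(mu), mu = mu, size = 1 / alpha)
             else rpois(length(mu), mu)
        setNames(as.integer(k), names(ab))
    })
}

#' Describe a replicated study layout
#'
#' A layout is the factorial frame of a reproducibility or interference
#' study: subjects crossed with laboratories, runs and technical replicates.
#' Subjects alternate between the UIP and non-UIP class.
#'
#' @param nSubjects,nRuns,nLabs,nReplicates positive design sizes.
#' @return a data.frame with one row per (subject, lab, run, replicate) cell.
#' @examples
#' nrow(studyLayout(9, nRuns = 3, nReplicates = 3))  # 81
#' @export
studyLayout <- function(nSubjects = 9L, nRuns = 3L, nLabs = 1L,
                        nReplicates = 3L) {
    stopIfNot(all(c(nSubjects, nRuns, nLabs, nReplicates) >= 1),
              "all layout dimensions must be >= 1")
    g <- expand.grid(
        replicate_index = seq_len(nReplicates),
        run_id = sprintf("R%d", seq_len(nRuns)),
        lab_id = sprintf("L%d", seq_len(nLabs)),
        subject_id = sprintf("S%02d", seq_len(nSubjects)),
        stringsAsFactors = FALSE)
    cls <- ifelse(as.integer(sub("S", "", g$subject_id)) %% 2L == 1L,
                  "UIP", "non-UIP")
    g$class_label <- cls
    g$tissue_role <- ifelse(cls == "UIP", "uip_tbb", "nonuip_tbb")
    g[, c("subject_id", "class_label", "tissue_role", "lab_id", "run_id",
          "replicate_index")]
}

#' Simulate a full replicated study
#'
#' Emits a count matrix for every cell of a study layout together with its
#' sample annotation and a truth record of every injected effect. Technical
#' structure is generated on the score scale - subject effects
#' (SD 0.5 score units, covering the score range), per-(lab, run) run
#' effects, lab effects and replicate residuals - and realized at the count
#' level as tilts of the sample's expression profile along the class
#' log-abundance axis (\code{classScoreGap} score units span the full
#' UIP vs non-UIP difference). Counts are then drawn negative-binomially per
#' replicate.
#'
#' @param layout data.frame from \code{\link{studyLayout}} (or with the same
#'   columns).
#' @param config a \code{GeneratorConfig}.
#' @param seed RNG seed; fixes profiles, effects and counts.
#' @param profiles optional profile list from \code{\link{makeProfiles}};
#'   built from \code{config} when omitted.
#' @param panel optional \code{GenePanel}; built from \code{config} when
#'   omitted.
#' @param model optional locked \code{ClassifierModel}. When supplied, the
#'   score-to-tilt conversion is calibrated against it: the display-score
#'   gap between the pure class profiles is measured under the model and
#'   used in place of \code{classScoreGap}, so an injected effect of u
#'   score units produces a measured score shift of about u units.
#' @return a \code{SummarizedExperiment} with assay \code{"counts"}, the
#'   annotation as \code{colData}, gene lengths as \code{rowData}, and
#'   \code{metadata()$truth} holding the injected effect values.
#' @examples
#' cfg <- generatorConfig(nGenes = 20, depth = 5e3)
#' se <- simulateStudy(studyLayout(2, 2, 1, 2), cfg, seed = 3)
#' dim(se)
#' @export
simulateStudy <- function(layout, config, seed, profiles = NULL,
                          panel = NULL, model = NULL) {
    stopIfNot(is.data.frame(layout) && nrow(layout) > 0,
              "layout must be a nonempty data.frame")
    stopIfNot(is(config, "GeneratorConfig"),
              "config must be a GeneratorConfig")
    seed <- as.integer(seed)
    if (is.null(panel)) panel <- makePanel(config@nGenes, seed = config@seed)
    if (is.null(profiles)) profiles <- makeProfiles(panel, config)
    axis <- classAxis(profiles)
    gap <- if (!is.null(model)) {
        expCounts <- vapply(profiles[c("uip_tbb", "nonuip_tbb")],
                            function(p) round(config@depth * abundance(p)),
                            numeric(length(axis)))
        s <- scoreCounts(model, expCounts)$score
        abs(s[1] - s[2])
    } else config@classScoreGap

    subjects <- unique(layout$subject_id)
    labs <- unique(layout$lab_id)
    cells <- unique(layout[, c("lab_id", "run_id")])

    withSeed(seed, {
        subjEff <- setNames(rnorm(length(subjects), 0, 0.5), subjects)
        labEff <- setNames(rnorm(length(labs), 0, config@labEffectSD), labs)
        runKey <- paste(cells$lab_id, cells$run_id, sep = ".")
        runEff <- setNames(rnorm(nrow(cells), 0, config@runEffectSD), runKey)
        resid <- rnorm(nrow(layout), 0, config@residualSD)
        storage <- sample(0:14, length(subjects), replace = TRUE)
        names(storage) <- subjects
        dv200 <- pmin(100, pmax(0, rnorm(length(subjects), 70, 5)))
        names(dv200) <- subjects

        ann <- layout
        ann$sample_id <- sprintf("%s_%s_%s_r%d", ann$subject_id, ann$lab_id,
                                 ann$run_id, ann$replicate_index)
        ann$input_mass_ng <- config@massRefNg
        ann$storage_days_cold <- storage[ann$subject_id]
        ann$dv200 <- dv200[ann$subject_id]

        counts <- matrix(0L, nrow = length(geneIds(panel)),
                         ncol = nrow(ann),
                         dimnames = list(geneIds(panel), ann$sample_id))
        shifts <- numeric(nrow(ann))
        for (i in seq_len(nrow(ann))) {
            role <- ann$tissue_role[i]
            stopIfNot(role %in% names(profiles),
                      paste("unknown tissue role:", role))
            sh <- subjEff[[ann$subject_id[i]]] +
                labEff[[ann$lab_id[i]]] +
                runEff[[paste(ann$lab_id[i], ann$run_id[i], sep = ".")]] +
                resid[i]
            shifts[i] <- sh
            p <- profiles[[role]]
            ab <- tiltAbundance(abundance(p), axis, sh, gap)
            # replicate libraries of one pooled material: technical
            # overdispersion only
            tilted <- new("ExpressionProfile", name = p@name,
                          abundance = ab,
                          dispersion = config@technicalDispersion)
            counts[, i] <- simulateCounts(tilted, config,
                                          seed = childSeed(seed, i),
                                          inputMassNg = ann$input_mass_ng[i])
        }
        truth <- list(
            subject_effect = as.list(subjEff),
            lab_effect = as.list(labEff),
            run_effect = as.list(runEff),
            residual = setNames(as.list(resid), ann$sample_id),
            total_shift = setNames(as.list(shifts), ann$sample_id),
            seed = seed)
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(ann, row.names = ann$sample_id),
            rowData = S4Vectors::DataFrame(
                gene_id = geneIds(panel),
                exonic_length = unname(exonicLength(panel))),
            metadata = list(truth = truth))
    })
}
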