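#' Marker-gene read-count proportion
#'
#' The proportion of blood-marker (hemoglobin-beta role) counts to total
#' counts: the gene-expression metric by which blood contamination of a
#' biopsy library is quantified. Around 0.3\% in clean biopsy pools and
#' above 17\% in pure blood.
#'
#' @param counts named count vector, or genes x samples matrix.
#' @param panel a \code{GenePanel} naming the marker gene.
#' @return proportion in [0, 1] (vector if a matrix was given).
#' @export
markerProportion <- function(counts, panel) {
    stopIfNot(is(panel, "GenePanel"), "panel must be a GenePanel")
    mk <- markerGene(panel)
    if (!is.null(dim(counts))) {
        tot <- colSums(counts)
        stopIfNot(all(tot > 0), "zero total counts")
        return(counts[mk, ] / tot)
    }
    tot <- sum(counts)
    stopIfNot(tot > 0, "zero total counts")
    unname(counts[mk] / tot)
}

#' Pure-diluent marker fraction implied by linear mixing
#'
#' Inverts the linear mixing relation \code{m = f * x + (1 - f) * b}: given
#' the baseline marker fraction \code{b} of clean tissue, the observed
#' marker fraction \code{m} of a mixture, and the diluent (blood) mass
#' fraction \code{f}, returns the implied marker fraction \code{x} of the
#' pure diluent. The printed anchors b = 0.003, m = 0.07 at f = 0.22 imply
#' x = 0.3075. A result outside [0, 1] is flagged inconsistent.
#'
#' @param baseline marker fraction b of the undiluted tissue.
#' @param mixture observed marker fraction m of the mixture.
#' @param fraction diluent mass fraction f in (0, 1].
#' @return implied pure-diluent marker fraction, with attribute
#'   \code{"inconsistent"} set to TRUE when it falls outside [0, 1].
#' @export
impliedPureBloodFraction <- function(baseline, mixture, fraction) {
    stopIfNot(fraction > 0 && fraction <= 1,
              "fraction must lie in (0, 1]")
    x <- (mixture - (1 - fraction) * baseline) / fraction
    inconsistent <- x < 0 || x > 1
    if (inconsistent)
        warning("implied pure-diluent marker fraction outside [0, 1]: ",
                "mixing arithmetic inconsistent", call. = FALSE)
    structure(x, inconsistent = inconsistent)
}

#' Blood-contamination titration of a UIP sample
#'
#' Simulates in silico mixtures of a UIP parent with whole-blood diluent
#' over a fraction grid, scores them, estimates the blood tolerance limit
#' by the concordance rule, and reports the mean marker-gene proportion at
#' each level (which is linear in the blood fraction).
#'
#' @param counts count matrix containing the parent and blood columns.
#' @param parent,blood column names.
#' @param fractions increasing blood mass fractions.
#' @param model a \code{ClassifierModel}.
#' @param panel a \code{GenePanel} (for the marker metric).
#' @param fractionJitterSD,depth,nSimulations,nBootstrap,seed simulation
#'   settings (see \code{\link{simulateMixtureGrid}}).
#' @return list of class \code{"InterferenceResult"} with elements
#'   \code{contaminant}, \code{levels} (per-fraction score and marker
#'   summaries), \code{curve}, and \code{lod}.
#' @export
bloodTitration <- function(counts, parent, blood, fractions, model, panel,
                           fractionJitterSD = 0.02, depth = 1e5,
                           nSimulations = 100L, nBootstrap = 200L,
                           seed = 1L) {
    stopIfNot(all(fractions >= 0 & fractions <= 1),
              "fractions must lie in [0, 1]")
    ens <- simulateMixtureGrid(counts, parent, blood, fractions,
                               fractionJitterSD = fractionJitterSD,
                               depth = depth, nSimulations = nSimulations,
                               seed = seed)
    ref <- scoreCounts(model, counts[, parent])$call
    res <- lodFromEnsembles(ens, model, ref, nBootstrap = nBootstrap,
                            seed = childSeed(seed, 999))
    levels <- do.call(rbind, lapply(names(ens), function(f) {
        sc <- scoreCounts(model, ens[[f]]$counts)$score
        data.frame(fraction = as.numeric(f),
                   mean_score = mean(sc), sd_score = sd(sc),
                   marker_proportion =
                       mean(markerProportion(ens[[f]]$counts, panel)))
    }))
    structure(list(contaminant = "blood", reference_call = ref,
                   levels = levels, curve = res$curve, lod = res$lod),
              class = "InterferenceResult")
}

#' Genomic-DNA spike-in test
#'
#' Simulates spiking each sample with genomic DNA at a stated fraction of
#' total nucleic-acid mass (default 30\%). gDNA contributes
#' exonic-length-proportional reads, but converts into a sequencing
#' library far less efficiently per unit mass than RNA in an RNA-seq
#' workflow; with relative read efficiency e, a gDNA mass fraction f
#' yields a gDNA read fraction \code{g = f e / (f e + 1 - f)}. The spiked
#' library's expected proportions are then
#' \code{(1 - g) * p_sample + g * p_gdna}. Both arms are simulated in
#' replicate, scored, and the condition effect is tested with a linear
#' model of score on condition with sample as a fixed factor.
#'
#' @param counts count matrix of the unspiked samples (columns).
#' @param gdnaProfile the gDNA \code{ExpressionProfile}.
#' @param model a \code{ClassifierModel}.
#' @param fraction gDNA mass fraction in [0, 1); default 0.30.
#' @param readEfficiency reads yielded per unit gDNA mass relative to RNA
#'   (default 0.02: DNA is a percent-level-efficiency substrate for an
#'   RNA library preparation).
#' @param nReplicates technical replicates per arm (>= 2).
#' @param depth reads per simulated library.
#' @param seed RNG seed.
#' @return list of class \code{"InterferenceResult"} with the per-arm score
#'   table, the condition effect estimate, its p-value, and the 0.05-level
#'   significance decision.
#' @export
gdnaSpikeTest <- function(counts, gdnaProfile, model, fraction = 0.30,
                          readEfficiency = 0.02, nReplicates = 3L,
                          depth = 1e5, seed = 1L) {
    stopIfNot(fraction >= 0 && fraction < 1, "fraction must lie in [0, 1)")
    stopIfNot(readEfficiency > 0, "readEfficiency must be positive")
    stopIfNot(nReplicates >= 2, "need >= 2 replicates per arm")
    counts <- asCountsMatrix(counts)
    pg <- abundance(gdnaProfile)
    readFraction <- fraction * readEfficiency /
        (fraction * readEfficiency + 1 - fraction)
    rows <- list()
    withSeed(seed, {
        for (s in colnames(counts)) {
            ps <- counts[, s] / sum(counts[, s])
            for (arm in c("control", "spiked")) {
                f <- if (arm == "spiked") readFraction else 0
                p <- (1 - f) * ps + f * pg
                for (r in seq_len(nReplicates)) {
                    k <- rmultinom(1, depth, p)[, 1]
                    names(k) <- rownames(counts)
                    rows[[length(rows) + 1L]] <- data.frame(
                        sample_id = s, condition = arm, replicate = r,
                        score = scoreCounts(model, k)$score)
                }
            }
        }
    })
    tab <- do.call(rbind, rows)
    form <- if (length(unique(tab$sample_id)) > 1)
        score ~ condition + sample_id else score ~ condition
    fit <- lm(form, data = tab)
    cf <- summary(fit)$coefficients
    est <- cf["conditionspiked", "Estimate"]
    p <- cf["conditionspiked", "Pr(>|t|)"]
    structure(list(contaminant = "gdna", levels = c(0, fraction),
                   scores = tab, effect = unname(est), p_value = unname(p),
                   significant = p < 0.05),
              class = "InterferenceResult")
}

#' RNA input-mass robustness test
#'
#' Simulates replicate libraries from each sample profile across a grid of
#' RNA input masses (defaults 5, 10, 15, 20 and 30 ng; effective depth and
#' depth jitter scale with mass), scores them, and fits a linear model of
#' score on mass with sample as a fixed factor. Reports the mass-slope
#' p-value and the pooled per-mass score SD.
#'
#' @param profiles named list of \code{ExpressionProfile}s, one per sample.
#' @param model a \code{ClassifierModel}.
#' @param config a \code{GeneratorConfig} (depth, mass scaling, jitter).
#' @param masses RNA input masses in ng.
#' @param nReplicates replicates per sample x mass cell.
#' @param seed RNG seed.
#' @return list of class \code{"InterferenceResult"} with per-mass score
#'   SDs, the mass-effect estimate and p-value, and the 0.05-level
#'   decision.
#' @export
inputMassTest <- function(profiles, model, config,
                          masses = c(5, 10, 15, 20, 30),
                          nReplicates = 3L, seed = 1L) {
    stopIfNot(all(masses > 0), "masses must be positive")
    rows <- list()
    i <- 0L
    for (s in names(profiles)) for (m in masses)
        for (r in seq_len(nReplicates)) {
            i <- i + 1L
            # replicate libraries of one pooled material
            tech <- new("ExpressionProfile",
                        name = profiles[[s]]@name,
                        abundance = abundance(profiles[[s]]),
                        dispersion = config@technicalDispersion)
            k <- simulateCounts(tech, config,
                                seed = childSeed(seed, i),
                                inputMassNg = m)
            rows[[i]] <- data.frame(sample_id = s, mass = m,
                                    replicate = r,
                                    score = scoreCounts(model, k)$score)
        }
    tab <- do.call(rbind, rows)
    fit <- lm(score ~ mass + sample_id, data = tab)
    cf <- summary(fit)$coefficients
    perMass <- do.call(rbind, lapply(sort(unique(tab$mass)), function(m) {
        sub <- tab[tab$mass == m, ]
        data.frame(mass = m,
                   sd_score = pooledSD(sub$score, sub$sample_id))
    }))
    structure(list(contaminant = "input_mass", levels = sort(masses),
                   scores = tab, per_mass = perMass,
                   effect = unname(cf["mass", "Estimate"]),
                   p_value = unname(cf["mass", "Pr(>|t|)"]),
                   significant = cf["mass", "Pr(>|t|)"] < 0.05),
              class = "InterferenceResult")
}

#' @export
print.InterferenceResult <- function(x, ...) {
    cat("InterferenceResult:", x$contaminant, "\n")
    if (!is.null(x$p_value))
        cat(sprintf("  effect %.4g, p = %.4g (%s at 0.05)\n", x$effect,
                    x$p_value,
                    if (x$significant) "significant" else "not significant"))
    if (!is.null(x$lod))
        cat("  tolerance limit f =", signif(lodValue(x$lod), 3), "\n")
    invisible(x)
}
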