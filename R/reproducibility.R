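#' Nested variance components of classifier scores
#'
#' Decomposes the score variability of a replicated study into nested
#' technical components:
#' \itemize{
#'   \item \strong{within-run SD}: pooled SD of replicate scores about
#'     their sample-by-run (per laboratory) cell means;
#'   \item \strong{run-to-run SD}: pooled SD of replicate scores about
#'     per-sample means - the nested total, which includes the within-run
#'     component;
#'   \item \strong{inter-lab SD}: pooled SD about per-sample means across
#'     laboratories (NA with a single laboratory);
#'   \item \strong{inter-class SD}: SD of per-sample mean scores across
#'     class-labelled samples, the biological comparator.
#' }
#' All pooled SDs use residual degrees of freedom (n minus the number of
#' groups).
#'
#' @param scores data.frame with columns \code{score}, \code{sample_id},
#'   and optionally \code{run_id}, \code{lab_id}, \code{class_label}.
#' @return a \code{\linkS4class{VarianceComponents}}.
#' @export
estimateVarianceComponents <- function(scores) {
    stopIfNot(is.data.frame(scores) &&
              all(c("score", "sample_id") %in% names(scores)),
              "scores must have score and sample_id columns")
    s <- scores$score
    hasRun <- "run_id" %in% names(scores)
    hasLab <- "lab_id" %in% names(scores) &&
        length(unique(scores$lab_id)) >= 2
    lab <- if ("lab_id" %in% names(scores)) scores$lab_id else "L1"

    withinRun <- NA_real_; nWithin <- 0L
    if (hasRun) {
        cell <- interaction(scores$sample_id, lab, scores$run_id,
                            drop = TRUE)
        if (length(s) - nlevels(cell) <= 0)
            stop("estimation failure for component 'within_run': ",
                 "no replication within sample-by-run cells",
                 call. = FALSE)
        withinRun <- pooledSD(s, cell)
        nWithin <- length(s)
    }

    bySample <- interaction(scores$sample_id, drop = TRUE)
    if (length(s) - nlevels(bySample) <= 0)
        stop("estimation failure for component 'run_to_run': ",
             "no sample has replicate measurements", call. = FALSE)
    runToRun <- pooledSD(s, bySample)

    interlab <- NA_real_; nInterlab <- 0L
    if (hasLab) {
        interlab <- pooledSD(s, bySample)
        nInterlab <- length(s)
    }

    interclass <- NA_real_; nInterclass <- 0L
    if ("class_label" %in% names(scores)) {
        keep <- scores$class_label %in% c("UIP", "non-UIP")
        if (any(keep)) {
            sm <- tapply(s[keep], scores$sample_id[keep], mean)
            if (length(sm) >= 2) {
                interclass <- sd(sm)
                nInterclass <- length(sm)
            }
        }
    }

    new("VarianceComponents",
        withinRunSD = withinRun, runToRunSD = runToRun,
        interlabSD = interlab, interclassSD = interclass,
        ci = matrix(numeric(0), nrow = 0, ncol = 2,
                    dimnames = list(NULL, c("lower", "upper"))),
        n = c(within_run = nWithin, run_to_run = length(s),
              interlab = nInterlab, interclass = nInterclass))
}

# Grouping used by a component's residual decomposition.
componentGroups <- function(scores, component) {
    lab <- if ("lab_id" %in% names(scores)) scores$lab_id else "L1"
    switch(component,
        within_run = interaction(scores$sample_id, lab, scores$run_id,
                                 drop = TRUE),
        run_to_run = ,
        interlab = interaction(scores$sample_id, drop = TRUE),
        stop("unknown component: ", component, call. = FALSE))
}

#' Residual-bootstrap CI for a variance component
#'
#' Computes a percentile 95\% confidence interval by residual bootstrap:
#' the residuals of the component's grouping model (scores about their
#' group means) are resampled with replacement, scores are rebuilt as
#' fitted values plus resampled residuals, and the component is
#' re-estimated. The bootstrap unit is the individual residual.
#'
#' @param scores data.frame as for
#'   \code{\link{estimateVarianceComponents}}.
#' @param component one of \code{"within_run"}, \code{"run_to_run"},
#'   \code{"interlab"}, \code{"interclass"}.
#' @param nBootstrap number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return named vector \code{c(lower, upper)}.
#' @export
sdBootstrapCi <- function(scores, component, nBootstrap = 1000L,
                          seed = 1L) {
    stopIfNot(nBootstrap >= 100, "nBootstrap must be >= 100")
    if (component == "interclass") {
        keep <- scores$class_label %in% c("UIP", "non-UIP")
        vals <- tapply(scores$score[keep], scores$sample_id[keep], mean)
        resid <- (vals - mean(vals)) * sqrt(length(vals) /
                                            (length(vals) - 1))
        boots <- withSeed(seed, vapply(seq_len(nBootstrap), function(b)
            sd(mean(vals) + sample(resid, replace = TRUE)), numeric(1)))
    } else {
        g <- componentGroups(scores, component)
        fitted <- tapply(scores$score, g, mean)[g]
        resid <- scores$score - fitted
        # leverage correction: group-mean residuals have variance deflated
        # by (n - k)/n, so inflate before resampling to keep the bootstrap
        # estimator centered
        n <- length(resid)
        df <- n - nlevels(droplevels(as.factor(g)))
        resid <- resid * sqrt(n / df)
        boots <- withSeed(seed, vapply(seq_len(nBootstrap), function(b) {
            pooledSD(fitted + sample(resid, replace = TRUE), g)
        }, numeric(1)))
    }
    ci <- unname(quantile(boots, c(0.025, 0.975)))
    c(lower = ci[1], upper = ci[2])
}

#' Noise tolerance of cross-validated classification
#'
#' Simulates increasing levels of random score variation on top of
#' cross-validated scores and measures the impact on sensitivity and
#' specificity. The maximum tolerable SD is the largest grid value up to
#' which neither sensitivity nor specificity drops more than \code{margin}
#' below its noise-free baseline.
#'
#' @param transformed VST matrix, genes x samples.
#' @param labels class labels.
#' @param sdGrid increasing grid of injected score SDs; must include 0.
#' @param margin maximum tolerated drop below baseline (absolute, on the
#'   [0, 1] sensitivity/specificity scale); default 0.05.
#' @param folds CV folds.
#' @param nRepeats noise draws averaged per grid point.
#' @param seed RNG seed.
#' @param penalty L2 regularization strength.
#' @return list with \code{grid} (data.frame of sd, sensitivity,
#'   specificity), \code{baseline}, \code{maxTolerableSD} and
#'   \code{margin}.
#' @export
noiseTolerance <- function(transformed, labels, sdGrid = seq(0, 1, 0.1),
                           margin = 0.05, folds = 5L, nRepeats = 20L,
                           seed = 1L, penalty = 0.01) {
    stopIfNot(0 %in% sdGrid, "sdGrid must include 0")
    stopIfNot(!is.unsorted(sdGrid, strictly = TRUE),
              "sdGrid must be strictly increasing")
    stopIfNot(margin > 0, "margin must be positive")
    cv <- cvScores(transformed, labels, folds = folds, seed = seed,
                   penalty = penalty)
    isU <- cv$label == "UIP"
    perf <- function(sc) c(sens = mean(sc[isU] > 0),
                           spec = mean(sc[!isU] <= 0))
    grid <- withSeed(childSeed(seed, 17), {
        do.call(rbind, lapply(sdGrid, function(sdv) {
            if (sdv == 0) {
                p <- perf(cv$score)
            } else {
                p <- rowMeans(vapply(seq_len(nRepeats), function(r)
                    perf(cv$score + rnorm(nrow(cv), 0, sdv)),
                    numeric(2)))
            }
            data.frame(sd = sdv, sensitivity = p[["sens"]],
                       specificity = p[["spec"]])
        }))
    })
    base <- grid[grid$sd == 0, ]
    ok <- grid$sensitivity >= base$sensitivity - margin &
          grid$specificity >= base$specificity - margin
    # largest SD before the first violation
    firstBad <- which(!ok)
    maxSD <- if (!length(firstBad)) max(grid$sd)
             else if (firstBad[1] == 1) 0
             else grid$sd[firstBad[1] - 1]
    list(grid = grid,
         baseline = c(sensitivity = base$sensitivity,
                      specificity = base$specificity),
         maxTolerableSD = maxSD, margin = margin)
}

#' Inter-laboratory concordance of classifier results
#'
#' Compares paired scores of shared samples measured in two laboratories:
#' the percentage of samples with matching binary calls, the R-squared of
#' lab-B on lab-A scores, and the pooled SD of the two measurements about
#' their per-sample means. Anti-correlated score vectors are flagged,
#' since R-squared alone cannot distinguish agreement from a sign flip.
#'
#' @param scoresA,scoresB numeric score vectors for the same samples in
#'   the same order (>= 2 samples).
#' @param boundary decision boundary (default 0).
#' @return list with \code{concordancePct}, \code{r2}, \code{pooledSD},
#'   \code{n}, and \code{flag} (\code{"ok"} or \code{"anticorrelated"}).
#' @export
interlabConcordance <- function(scoresA, scoresB, boundary = 0) {
    stopIfNot(length(scoresA) == length(scoresB),
              "score vectors must be paired")
    stopIfNot(length(scoresA) >= 2, "need at least 2 shared samples")
    callA <- scoresA > boundary
    callB <- scoresB > boundary
    r <- stats::cor(scoresA, scoresB)
    pairMean <- (scoresA + scoresB) / 2
    pooled <- sqrt(sum((scoresA - pairMean)^2 + (scoresB - pairMean)^2) /
                   length(scoresA))
    list(concordancePct = 100 * mean(callA == callB),
         r2 = r^2,
         pooledSD = pooled,
         n = length(scoresA),
         flag = if (is.finite(r) && r < 0) "anticorrelated" else "ok")
}

#' Storage-stability ANOVA of RNA quality
#'
#' One-way analysis of variance of DV200 (the percentage of RNA fragments
#' longer than 200 nucleotides) across cold-storage time bins: the test of
#' whether storage duration degrades RNA quality.
#'
#' @param dv200 numeric DV200 values.
#' @param bins storage-time bin labels, parallel to \code{dv200} (>= 2
#'   bins with >= 2 values each).
#' @return list with \code{F}, \code{p_value}, \code{df}, and the
#'   per-bin means.
#' @export
storageAnova <- function(dv200, bins) {
    stopIfNot(length(dv200) == length(bins),
              "dv200 and bins must be parallel")
    bins <- factor(bins)
    tabn <- table(bins)
    if (nlevels(bins) < 2 || any(tabn < 2))
        stop("estimation failure: need >= 2 bins with >= 2 values each",
             call. = FALSE)
    fit <- lm(dv200 ~ bins)
    a <- suppressWarnings(anova(fit))
    ssB <- a$`Sum Sq`[1]
    if (ssB <= .Machine$double.eps * sum(dv200^2)) {
        f <- 0; p <- 1
    } else {
        f <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
    }
    list(F = f, p_value = p, df = a$Df,
         bin_means = tapply(dv200, bins, mean))
}
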