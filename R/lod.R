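#' Concordance curve of simulated mixtures
#'
#' Scores every simulated mixture at each grid fraction with a locked model
#' and records the frequency of calls concordant with the parent's
#' reference label.
#'
#' @param ensembles named list (names = fractions) as produced by
#'   \code{\link{simulateMixtureGrid}}, or of bare count matrices.
#' @param model a \code{ClassifierModel}.
#' @param referenceCall \code{"UIP"} or \code{"non-UIP"}: the parent's
#'   reference label.
#' @return data.frame with columns \code{fraction}, \code{concordance},
#'   \code{n}, carrying the reference call as an attribute.
#' @export
concordanceCurve <- function(ensembles, model, referenceCall) {
    stopIfNot(length(ensembles) >= 2, "need at least 2 grid points")
    stopIfNot(referenceCall %in% c("UIP", "non-UIP"),
              "referenceCall must be 'UIP' or 'non-UIP'")
    fractions <- as.numeric(names(ensembles))
    stopIfNot(all(is.finite(fractions)) &&
              !is.unsorted(fractions, strictly = TRUE),
              "ensemble names must form a strictly increasing fraction grid")
    rows <- lapply(seq_along(ensembles), function(i) {
        e <- ensembles[[i]]
        m <- if (is.list(e) && !is.null(e$counts)) e$counts else e
        if (is.null(dim(m)) || ncol(m) == 0)
            stop("empty ensemble at fraction ", fractions[i], call. = FALSE)
        calls <- scoreCounts(model, m)$call
        data.frame(fraction = fractions[i],
                   concordance = mean(calls == referenceCall),
                   n = length(calls))
    })
    curve <- do.call(rbind, rows)
    attr(curve, "referenceCall") <- referenceCall
    curve
}

# Isotonic nonincreasing smoothing of a concordance curve.
isotonicDecreasing <- function(fraction, concordance) {
    -isoreg(fraction, -concordance)$yf
}

#' Limit of detection by the 90\%-concordance rule
#'
#' Applies isotonic (nonincreasing) regression to the concordance
#' frequencies, then reports the most diluted (largest) grid fraction at
#' which the smoothed concordance still reaches the threshold. If no grid
#' point qualifies the estimate is 0 with flag
#' \code{"none_above_threshold"}; if every point qualifies the largest grid
#' fraction is returned with flag \code{"saturated"}.
#'
#' @param curve data.frame from \code{\link{concordanceCurve}} (columns
#'   \code{fraction}, \code{concordance}).
#' @param threshold concordance threshold in (0.5, 1); default 0.90.
#' @return an \code{\linkS4class{LODEstimate}}.
#' @export
estimateLod <- function(curve, threshold = 0.90) {
    stopIfNot(is.data.frame(curve) &&
              all(c("fraction", "concordance") %in% names(curve)),
              "curve must have fraction and concordance columns")
    stopIfNot(!is.unsorted(curve$fraction, strictly = TRUE),
              "fraction grid must be strictly increasing")
    stopIfNot(all(curve$concordance >= 0 & curve$concordance <= 1),
              "concordance values must lie in [0, 1]")
    sm <- isotonicDecreasing(curve$fraction, curve$concordance)
    ok <- sm >= threshold
    if (!any(ok)) {
        est <- 0; flag <- "none_above_threshold"
    } else if (all(ok)) {
        est <- max(curve$fraction); flag <- "saturated"
    } else {
        est <- max(curve$fraction[ok]); flag <- "ok"
    }
    new("LODEstimate", estimate = est, lower = NA_real_, upper = NA_real_,
        threshold = threshold, method = "concordance", nBootstrap = 0L,
        flag = flag)
}

#' Bootstrap confidence interval for a concordance-rule LOD
#'
#' Resamples the simulated calls within each grid point with replacement
#' and re-applies the threshold rule. Because the per-point data are
#' Bernoulli concordance indicators, resampling n of them with replacement
#' is exactly a Binomial(n, c-hat)/n draw, which is how the resampling is
#' realized. The 95\% CI is the percentile interval of the bootstrap LOD
#' distribution.
#'
#' @param curve data.frame from \code{\link{concordanceCurve}} with columns
#'   \code{fraction}, \code{concordance}, \code{n}.
#' @param threshold concordance threshold; default 0.90.
#' @param nBootstrap number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return an \code{LODEstimate} with CI filled in.
#' @export
lodBootstrapCi <- function(curve, threshold = 0.90, nBootstrap = 500L,
                           seed = 1L) {
    stopIfNot(nBootstrap >= 100, "nBootstrap must be >= 100")
    stopIfNot("n" %in% names(curve), "curve must carry per-point n")
    point <- estimateLod(curve, threshold)
    k <- nrow(curve)
    boots <- withSeed(seed, {
        vapply(seq_len(nBootstrap), function(b) {
            cb <- rbinom(k, curve$n, curve$concordance) / curve$n
            sm <- isotonicDecreasing(curve$fraction, cb)
            ok <- sm >= threshold
            if (!any(ok)) 0 else max(curve$fraction[ok])
        }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975)))
    new("LODEstimate", estimate = point@estimate,
        lower = min(ci[1], point@estimate),
        upper = max(ci[2], point@estimate),
        threshold = threshold, method = "concordance",
        nBootstrap = as.integer(nBootstrap), flag = point@flag)
}

#' Full concordance-rule LOD from mixture ensembles
#'
#' Convenience wrapper: builds the concordance curve from scored ensembles
#' and attaches the bootstrap CI.
#'
#' @inheritParams concordanceCurve
#' @inheritParams lodBootstrapCi
#' @return list with \code{curve} (data.frame) and \code{lod}
#'   (\code{LODEstimate}).
#' @export
lodFromEnsembles <- function(ensembles, model, referenceCall,
                             threshold = 0.90, nBootstrap = 500L,
                             seed = 1L) {
    curve <- concordanceCurve(ensembles, model, referenceCall)
    list(curve = curve,
         lod = lodBootstrapCi(curve, threshold = threshold,
                              nBootstrap = nBootstrap, seed = seed))
}

#' Limit of detection by spline boundary crossing
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized cross
#' validation) to scores measured at a set of dilution fractions and
#' locates, by root finding on the fitted curve, the smallest fraction at
#' which the fit crosses the decision boundary away from the parent's side.
#' If the fitted curve never crosses within the observed range the result
#' is flagged \code{"no_crossing"} with an undefined estimate.
#'
#' @param fractions dilution fractions (>= 4 distinct values).
#' @param scores display-scale scores at those fractions (replicates
#'   allowed: supply repeated fractions).
#' @param boundary decision boundary (default 0).
#' @return an \code{LODEstimate} with method \code{"spline"}.
#' @export
splineCrossing <- function(fractions, scores, boundary = 0) {
    stopIfNot(length(fractions) == length(scores),
              "fractions and scores must be parallel")
    stopIfNot(length(unique(fractions)) >= 4,
              "need at least 4 distinct fractions")
    fit <- tryCatch(
        smooth.spline(fractions, scores),
        error = function(e) smooth.spline(fractions, scores, df = 3))
    lo <- min(fractions); hi <- max(fractions)
    grid <- seq(lo, hi, length.out = 512)
    pred <- predict(fit, grid)$y
    parentSide <- sign(pred[1] - boundary)
    if (parentSide == 0) parentSide <- 1
    crossed <- which(sign(pred - boundary) == -parentSide)
    if (!length(crossed))
        return(new("LODEstimate", estimate = NA_real_, lower = NA_real_,
                   upper = NA_real_, threshold = NA_real_,
                   method = "spline", nBootstrap = 0L,
                   flag = "no_crossing"))
    j <- crossed[1]
    root <- uniroot(function(f) predict(fit, f)$y - boundary,
                    lower = grid[max(1, j - 1)], upper = grid[j],
                    extendInt = "no", tol = 1e-8)$root
    new("LODEstimate", estimate = root, lower = NA_real_, upper = NA_real_,
        threshold = NA_real_, method = "spline", nBootstrap = 0L,
        flag = "ok")
}
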