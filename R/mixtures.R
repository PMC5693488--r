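#' Specify an in silico mixture experiment
#'
#' A mixture spec names a parent and a diluent sample, the diluent mass
#' fraction, the technical jitter on that fraction, and the Monte-Carlo
#' settings. Equal RNA mass is assumed to contribute equal expected reads,
#' so mass fractions act directly on count proportions.
#'
#' @param parent,diluent column names of the two samples in the count
#'   matrix.
#' @param fraction diluent mass fraction f in [0, 1].
#' @param fractionJitterSD SD of the Gaussian jitter applied to f per
#'   simulation (truncated to [0, 1]).
#' @param depth total reads drawn per simulated mixture.
#' @param nSimulations number of simulated mixtures (>= 1).
#' @param seed RNG seed.
#' @return a validated list of class \code{"MixtureSpec"}.
#' @export
mixtureSpec <- function(parent, diluent, fraction, fractionJitterSD = 0.02,
                        depth = 1e5, nSimulations = 100L, seed = 1L) {
    stopIfNot(fraction >= 0 && fraction <= 1, "fraction must lie in [0, 1]")
    stopIfNot(fractionJitterSD >= 0, "fractionJitterSD must be >= 0")
    stopIfNot(nSimulations >= 1, "nSimulations must be >= 1")
    stopIfNot(depth > 0, "depth must be positive")
    structure(list(parent = parent, diluent = diluent, fraction = fraction,
                   fractionJitterSD = fractionJitterSD, depth = depth,
                   nSimulations = as.integer(nSimulations),
                   seed = as.integer(seed)),
              class = "MixtureSpec")
}

#' Expected per-gene proportions of a two-sample mixture
#'
#' Converts each sample's counts to proportions and mixes them linearly by
#' mass fraction: \code{p_mix = (1 - f) * p_parent + f * p_diluent}. Reads
#' are assumed proportional to contributed RNA mass. The worked anchor: a
#' parent with marker proportion 0.003 mixed with 22\% blood at marker
#' proportion 0.3075 yields a mixture marker proportion of 0.07.
#'
#' @param parentCounts,diluentCounts nonnegative count vectors over the
#'   same genes; neither may be all zero.
#' @param fraction diluent mass fraction f in [0, 1].
#' @return named vector of mixture proportions summing to 1.
#' @export
mixProportions <- function(parentCounts, diluentCounts, fraction) {
    stopIfNot(fraction >= 0 && fraction <= 1, "fraction must lie in [0, 1]")
    stopIfNot(all(parentCounts >= 0) && all(diluentCounts >= 0),
              "counts must be nonnegative")
    stopIfNot(length(parentCounts) == length(diluentCounts),
              "parent and diluent must cover the same genes")
    if (sum(parentCounts) == 0 || sum(diluentCounts) == 0)
        stop("all-zero sample cannot be mixed", call. = FALSE)
    pp <- parentCounts / sum(parentCounts)
    pd <- diluentCounts / sum(diluentCounts)
    (1 - fraction) * pp + fraction * pd
}

#' Simulate an ensemble of mixture count vectors
#'
#' For each simulation a realized fraction f' is drawn from
#' Normal(f, sigma_f) truncated to [0, 1], and a mixture library is drawn
#' as Multinomial(depth, p_mix(f')). The multinomial layer models only
#' measurement sampling: the parent and diluent counts already carry
#' biological dispersion, so no extra overdispersion is added. When
#' technical replicates of the parent or diluent are supplied (matrix
#' columns), simulations cycle through all possible parent x diluent
#' replicate pairs.
#'
#' @param spec a \code{\link{mixtureSpec}}.
#' @param counts count matrix whose columns include the parent and diluent
#'   samples (replicate columns may be passed as
#'   \code{"id.1"}, \code{"id.2"}, ... via \code{parentCols}).
#' @param parentCols,diluentCols optional explicit replicate column names;
#'   default is the single column the mixture spec names.
#' @return list with \code{counts} (genes x nSimulations matrix),
#'   \code{fraction} (realized f' per simulation), and \code{pair}
#'   (parent/diluent replicate labels per simulation).
#' @export
simulateMixture <- function(spec, counts, parentCols = spec$parent,
                            diluentCols = spec$diluent) {
    stopIfNot(inherits(spec, "MixtureSpec"), "spec must be a MixtureSpec")
    counts <- asCountsMatrix(counts)
    missing <- setdiff(c(parentCols, diluentCols), colnames(counts))
    if (length(missing))
        stop("samples absent from count matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    pairs <- expand.grid(parent = parentCols, diluent = diluentCols,
                         stringsAsFactors = FALSE)
    nS <- spec$nSimulations
    pairIdx <- rep_len(seq_len(nrow(pairs)), nS)
    withSeed(spec$seed, {
        f <- rnorm(nS, spec$fraction, spec$fractionJitterSD)
        f <- pmin(1, pmax(0, f))
        sim <- matrix(0L, nrow = nrow(counts), ncol = nS,
                      dimnames = list(rownames(counts),
                                      sprintf("sim_%03d", seq_len(nS))))
        for (i in seq_len(nS)) {
            pr <- pairs[pairIdx[i], ]
            p <- mixProportions(counts[, pr$parent], counts[, pr$diluent],
                                f[i])
            sim[, i] <- rmultinom(1, size = spec$depth, prob = p)[, 1]
        }
        list(counts = sim, fraction = f,
             pair = data.frame(parent = pairs$parent[pairIdx],
                               diluent = pairs$diluent[pairIdx],
                               stringsAsFactors = FALSE))
    })
}

#' Simulate mixture ensembles over a fraction grid
#'
#' Runs \code{\link{simulateMixture}} at each fraction of a grid with
#' deterministically derived per-point seeds, producing the input for
#' \code{\link{concordanceCurve}}.
#'
#' @inheritParams simulateMixture
#' @param fractions increasing vector of diluent mass fractions.
#' @param fractionJitterSD,depth,nSimulations,seed as in
#'   \code{\link{mixtureSpec}}.
#' @param parent,diluent sample column names.
#' @return named list (names = fractions) of simulateMixture results.
#' @export
simulateMixtureGrid <- function(counts, parent, diluent, fractions,
                                fractionJitterSD = 0.02, depth = 1e5,
                                nSimulations = 100L, seed = 1L,
                                parentCols = parent,
                                diluentCols = diluent) {
    stopIfNot(!is.unsorted(fractions, strictly = TRUE),
              "fractions must be strictly increasing")
    out <- lapply(seq_along(fractions), function(i) {
        sp <- mixtureSpec(parent, diluent, fractions[i],
                          fractionJitterSD = fractionJitterSD,
                          depth = depth, nSimulations = nSimulations,
                          seed = childSeed(seed, i))
        simulateMixture(sp, counts, parentCols = parentCols,
                        diluentCols = diluentCols)
    })
    names(out) <- as.character(fractions)
    out
}
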