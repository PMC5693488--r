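#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample by the median-of-ratios
#' method: for each gene with strictly positive counts in every sample, the
#' ratio of its count to its across-sample geometric mean is formed, and the
#' per-sample median of these ratios is the size factor. Factors are then
#' rescaled to geometric mean 1. Genes with any zero are excluded, the
#' standard median-of-ratios convention.
#'
#' @param counts nonnegative matrix, genes x samples (>= 2 samples), or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay.
#' @return named numeric vector of size factors with geometric mean 1.
#' @examples
#' m <- cbind(a = c(2, 6), b = c(4, 12))
#' estimateSizeFactors(m)  # 0.7071, 1.4142
#' @export
estimateSizeFactors <- function(counts) {
    counts <- asCountsMatrix(counts)
    stopIfNot(ncol(counts) >= 2, "need at least 2 samples")
    stopIfNot(all(counts >= 0), "counts must be nonnegative")
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("size-factor estimation failed: no gene has positive counts ",
             "in every sample", call. = FALSE)
    lk <- log(counts[pos, , drop = FALSE])
    logGeo <- rowMeans(lk)
    s <- exp(apply(lk - logGeo, 2, median))
    s <- s / exp(mean(log(s)))
    setNames(s, colnames(counts))
}

#' Pooled method-of-moments dispersion estimate
#'
#' Estimates a single negative-binomial dispersion alpha from normalized
#' counts by pooling the per-gene moment estimator of
#' (variance - mean) / mean^2, clipped at zero. Used to parameterize the
#' closed-form variance-stabilizing transform; no trend fitting or
#' shrinkage is attempted.
#'
#' @param counts nonnegative matrix, genes x samples (>= 2 samples).
#' @param sizeFactors size factors from \code{\link{estimateSizeFactors}};
#'   defaults to all ones.
#' @return a single dispersion estimate >= 0.
#' @export
estimateDispersion <- function(counts, sizeFactors = NULL) {
    counts <- asCountsMatrix(counts)
    stopIfNot(ncol(counts) >= 2, "need at least 2 samples")
    if (is.null(sizeFactors)) sizeFactors <- rep(1, ncol(counts))
    q <- sweep(counts, 2, sizeFactors, "/")
    mu <- rowMeans(q)
    v <- apply(q, 1, var)
    keep <- mu > 0
    if (!any(keep)) return(0)
    max(0, mean((v[keep] - mu[keep]) / mu[keep]^2))
}

#' Closed-form variance-stabilizing transform
#'
#' Applies the exact variance-stabilizing integral for negative-binomial
#' counts with variance mu + alpha * mu^2: each normalized count
#' q = count / size factor maps to \code{(2/sqrt(alpha)) * asinh(sqrt(alpha
#' * q))}, with the continuous limit \code{2 * sqrt(q)} at alpha = 0. The
#' transform is strictly increasing in q and fixes 0.
#'
#' @param counts nonnegative matrix, genes x samples, or a vector.
#' @param sizeFactors per-sample size factors (default all ones).
#' @param alpha dispersion >= 0.
#' @return matrix (or vector) of transformed values.
#' @examples
#' vstTransform(matrix(1), alpha = 1)  # 2 * asinh(1) = 1.7627
#' @export
vstTransform <- function(counts, sizeFactors = NULL, alpha = 0) {
    vec <- is.null(dim(counts))
    if (vec) counts <- matrix(counts, ncol = 1,
                              dimnames = list(names(counts), NULL))
    counts <- asCountsMatrix(counts, integerOnly = FALSE)
    stopIfNot(all(counts >= 0), "counts must be nonnegative")
    stopIfNot(length(alpha) == 1L && alpha >= 0, "alpha must be >= 0")
    if (is.null(sizeFactors)) sizeFactors <- rep(1, ncol(counts))
    stopIfNot(all(sizeFactors > 0), "size factors must be positive")
    q <- sweep(counts, 2, sizeFactors, "/")
    out <- if (alpha > 0) (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))
           else 2 * sqrt(q)
    if (vec) out[, 1] else out
}

# Coerce SummarizedExperiment or data.frame input to a counts matrix.
asCountsMatrix <- function(x, integerOnly = FALSE) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    x <- as.matrix(x)
    stopIfNot(is.numeric(x), "counts must be numeric")
    x
}
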