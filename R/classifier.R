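#' Train a surrogate locked linear classifier
#'
#' Fits an L2-penalized logistic regression of class on variance-stabilized
#' features (UIP is the positive direction) and locks it: the returned
#' \code{\linkS4class{ClassifierModel}} is immutable and scoring is a pure
#' function of it. The raw linear score is affinely calibrated so that the
#' 1st-99th percentile range of training scores spans 7 display units and
#' the loss-optimal logistic threshold (raw score 0) maps to display score
#' 0, the decision boundary. Ties at the boundary call non-UIP: the
#' classifier is built to resist false positives.
#'
#' @param transformed numeric matrix of VST values, genes x samples.
#' @param labels character/factor of \code{"UIP"} / \code{"non-UIP"}, one
#'   per sample; both classes must have >= 3 samples.
#' @param penalty L2 regularization strength (glmnet lambda).
#' @param seed stored in metadata; the fit itself is deterministic.
#' @param refLogMeans optional per-gene reference log geometric means of
#'   normalized training counts, frozen into the model so raw counts can be
#'   scored later (see \code{\link{scoreCounts}}).
#' @param alpha VST dispersion frozen into the model.
#' @return a locked \code{ClassifierModel}.
#' @seealso \code{\link{trainFromCounts}} for the counts-in convenience
#'   wrapper.
#' @export
trainClassifier <- function(transformed, labels, penalty = 0.01, seed = 1L,
                            refLogMeans = NULL, alpha = 0) {
    transformed <- as.matrix(transformed)
    labels <- as.character(labels)
    stopIfNot(length(labels) == ncol(transformed),
              "one label per sample required")
    stopIfNot(all(labels %in% c("UIP", "non-UIP")),
              "labels must be 'UIP' or 'non-UIP'")
    nU <- sum(labels == "UIP"); nN <- sum(labels == "non-UIP")
    if (nU < 3 || nN < 3)
        stop("both classes must be present with >= 3 samples each",
             call. = FALSE)
    x <- t(transformed)
    y <- as.integer(labels == "UIP")
    lambdas <- sort(unique(penalty * c(100, 10, 1)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambdas, standardize = FALSE,
                          thresh = 1e-12)
    cf <- as.numeric(coef(fit, s = penalty))
    b <- cf[1]
    w <- setNames(cf[-1], rownames(transformed))
    raw <- drop(x %*% w) + b
    span <- diff(quantile(raw, c(0.01, 0.99), names = FALSE))
    sc <- if (span > 0) 7 / span else 1
    if (is.null(refLogMeans))
        refLogMeans <- setNames(rep(NA_real_, length(w)), names(w))
    new("ClassifierModel",
        weights = w, intercept = b, scale = sc, boundary = 0,
        refLogMeans = refLogMeans[names(w)], dispersion = alpha,
        metadata = list(nUIP = nU, nNonUIP = nN, penalty = penalty,
                        seed = as.integer(seed)))
}

#' Normalize, transform and train in one step
#'
#' Convenience wrapper running the full input contract of the classifier:
#' median-of-ratios size factors, pooled dispersion estimate, closed-form
#' VST, then \code{\link{trainClassifier}}. The per-gene log geometric means
#' of normalized training counts and the dispersion are frozen into the
#' model so that new raw-count samples can be scored single-sample.
#'
#' @param counts integer matrix, genes x samples.
#' @param labels class labels, one per sample.
#' @param penalty L2 regularization strength.
#' @param seed stored in metadata.
#' @return a locked \code{ClassifierModel}.
#' @export
trainFromCounts <- function(counts, labels, penalty = 0.01, seed = 1L) {
    counts <- asCountsMatrix(counts)
    sf <- estimateSizeFactors(counts)
    alpha <- estimateDispersion(counts, sf)
    q <- sweep(counts, 2, sf, "/")
    lref <- rowMeans(log(q))
    lref[!is.finite(lref)] <- NA_real_
    vst <- vstTransform(counts, sf, alpha)
    trainClassifier(vst, labels, penalty = penalty, seed = seed,
                    refLogMeans = lref, alpha = alpha)
}

#' Score transformed samples with a locked model
#'
#' Computes the calibrated display score \code{scale * (w . x + b)} and the
#' binary call for one or more already-transformed sample vectors. Scoring
#' is pure: the model is never mutated, and batching or ordering cannot
#' change results. A score strictly above the boundary calls UIP; ties call
#' non-UIP.
#'
#' @param model a \code{ClassifierModel}.
#' @param x named numeric vector (one sample) or matrix (genes x samples)
#'   of VST values; gene set must match the model.
#' @return data.frame with columns \code{sample_id}, \code{score},
#'   \code{call}.
#' @export
scoreSample <- function(model, x) {
    stopIfNot(is(model, "ClassifierModel"),
              "model must be a ClassifierModel")
    if (is.null(dim(x)))
        x <- matrix(x, ncol = 1,
                    dimnames = list(names(x), "sample_1"))
    stopIfNot(nrow(x) == length(model@weights),
              "feature vector length does not match the panel")
    if (!is.null(rownames(x))) {
        stopIfNot(setequal(rownames(x), names(model@weights)),
                  "feature genes do not match the model's panel")
        x <- x[names(model@weights), , drop = FALSE]
    }
    # fixed per-sample summation order so batching cannot perturb scores
    raw <- colSums(x * model@weights) + model@intercept
    score <- model@scale * raw
    ids <- colnames(x)
    if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(score))
    data.frame(sample_id = ids, score = unname(score),
               call = ifelse(score > model@boundary, "UIP", "non-UIP"),
               stringsAsFactors = FALSE)
}

#' Score raw count samples with a locked model
#'
#' Applies the model's frozen preprocessing to raw counts - a single-sample
#' median-of-ratios size factor against the stored reference log geometric
#' means, then the closed-form VST at the stored dispersion - and scores
#' the result. This is the production-style path: a locked model carries
#' everything needed to score one new library at a time.
#'
#' @param model a \code{ClassifierModel} trained via
#'   \code{\link{trainFromCounts}} (reference means present).
#' @param counts named integer vector or genes x samples matrix of raw
#'   counts.
#' @return data.frame with columns \code{sample_id}, \code{score},
#'   \code{call}.
#' @export
scoreCounts <- function(model, counts) {
    stopIfNot(is(model, "ClassifierModel"),
              "model must be a ClassifierModel")
    if (is.null(dim(counts)))
        counts <- matrix(counts, ncol = 1,
                         dimnames = list(names(counts), "sample_1"))
    counts <- asCountsMatrix(counts, integerOnly = FALSE)
    stopIfNot(nrow(counts) == length(model@weights),
              "count vector length does not match the panel")
    if (!is.null(rownames(counts)))
        counts <- counts[names(model@weights), , drop = FALSE]
    ref <- model@refLogMeans
    stopIfNot(any(is.finite(ref)),
              "model carries no preprocessing reference; train via trainFromCounts")
    sf <- vapply(seq_len(ncol(counts)), function(j) {
        k <- counts[, j]
        use <- k > 0 & is.finite(ref)
        stopIfNot(any(use), "sample shares no positive genes with reference")
        exp(median(log(k[use]) - ref[use]))
    }, numeric(1))
    vst <- vstTransform(counts, sf, model@dispersion)
    rownames(vst) <- rownames(counts)
    scoreSample(model, vst)
}

#' Cross-validated scores
#'
#' Produces out-of-fold display scores by stratified k-fold cross
#' validation: each fold's samples are scored by a model trained on the
#' remaining folds with the same penalty.
#'
#' @param transformed VST matrix, genes x samples.
#' @param labels class labels.
#' @param folds number of folds (>= 2, <= smallest class size).
#' @param seed RNG seed for the stratified fold assignment.
#' @param penalty L2 regularization strength.
#' @return data.frame with columns \code{sample_id}, \code{label},
#'   \code{fold}, \code{score}, \code{call}.
#' @export
cvScores <- function(transformed, labels, folds = 5L, seed = 1L,
                     penalty = 0.01) {
    transformed <- as.matrix(transformed)
    labels <- as.character(labels)
    stopIfNot(folds >= 2, "folds must be >= 2")
    minClass <- min(table(labels))
    if (folds > minClass)
        stop("folds exceeds the size of the smallest class", call. = FALSE)
    n <- ncol(transformed)
    fold <- integer(n)
    withSeed(seed, {
        for (cl in unique(labels)) {
            idx <- sample(which(labels == cl))
            fold[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    out <- vector("list", folds)
    for (k in seq_len(folds)) {
        test <- fold == k
        m <- trainClassifier(transformed[, !test, drop = FALSE],
                             labels[!test], penalty = penalty, seed = seed)
        sc <- scoreSample(m, transformed[, test, drop = FALSE])
        sc$sample_id <- colnames(transformed)[test]
        sc$label <- labels[test]
        sc$fold <- k
        out[[k]] <- sc
    }
    res <- do.call(rbind, out)
    res[order(match(res$sample_id, colnames(transformed))),
        c("sample_id", "label", "fold", "score", "call")]
}

#' Cross-validated sensitivity and specificity
#'
#' Stratified k-fold cross validation of the surrogate classifier:
#' sensitivity is the fraction of UIP samples called UIP out of fold,
#' specificity the fraction of non-UIP samples called non-UIP.
#'
#' @inheritParams cvScores
#' @return list with \code{sensitivity}, \code{specificity} (both in
#'   [0, 1]) and the per-sample \code{scores} data.frame.
#' @export
evaluateCV <- function(transformed, labels, folds = 5L, seed = 1L,
                       penalty = 0.01) {
    sc <- cvScores(transformed, labels, folds = folds, seed = seed,
                   penalty = penalty)
    list(
        sensitivity = mean(sc$call[sc$label == "UIP"] == "UIP"),
        specificity = mean(sc$call[sc$label == "non-UIP"] == "non-UIP"),
        scores = sc)
}
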