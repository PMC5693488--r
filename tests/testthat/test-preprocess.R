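test_that("size factors follow the median-of-ratios contract", {
    m <- cbind(s1 = c(5L, 10L, 3L), s2 = c(5L, 10L, 3L))
    expect_equal(unname(estimateSizeFactors(m)), c(1, 1))

    # hand-computed two-gene case
    m2 <- cbind(a = c(2, 6), b = c(4, 12))
    expect_equal(unname(estimateSizeFactors(m2)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

    # scale equivariance: doubling one sample doubles its relative factor
    set.seed(1)
    m3 <- matrix(rpois(40, 50), nrow = 10)
    s <- estimateSizeFactors(m3)
    m3d <- m3; m3d[, 2] <- m3d[, 2] * 2L
    sd2 <- estimateSizeFactors(m3d)
    expect_equal(unname((sd2[2] / sd2[1]) / (s[2] / s[1])), 2,
                 tolerance = 1e-9)

    # no gene positive everywhere
    bad <- cbind(c(0L, 5L), c(3L, 0L))
    expect_error(estimateSizeFactors(bad), "no gene")
})

test_that("size factors agree with brute-force and DESeq2 oracles", {
    bruteForce <- function(m) {
        geo <- apply(m, 1, function(r) exp(mean(log(r))))
        keep <- apply(m, 1, function(r) all(r > 0))
        s <- vapply(seq_len(ncol(m)), function(j)
            median(m[keep, j] / geo[keep]), numeric(1))
        s / exp(mean(log(s)))
    }
    set.seed(42)
    for (i in 1:10) {
        m <- matrix(rpois(20, 30) + 1L, nrow = 5, ncol = 4)
        expect_equal(unname(estimateSizeFactors(m)), bruteForce(m),
                     tolerance = 1e-12)
    }

    set.seed(7)
    m <- matrix(rpois(200, 60) + 1L, nrow = 50, ncol = 4)
    ds <- DESeq2::estimateSizeFactorsForMatrix(m)
    ds <- ds / exp(mean(log(ds)))
    expect_equal(unname(estimateSizeFactors(m)), unname(ds),
                 tolerance = 1e-8)
})

test_that("pooled dispersion estimation recovers the truth", {
    set.seed(3)
    pois <- matrix(rpois(200 * 50, 100), nrow = 200)
    expect_lt(estimateDispersion(pois), 0.01)

    nb <- matrix(rnbinom(200 * 50, mu = 100, size = 1 / 0.05), nrow = 200)
    a <- estimateDispersion(nb)
    expect_gt(a, 0.03); expect_lt(a, 0.07)

    expect_identical(estimateDispersion(matrix(5L, 10, 4)), 0)
})

test_that("the VST matches its closed form and analytic limits", {
    expect_identical(unname(vstTransform(0, alpha = 1)), 0)
    expect_identical(unname(vstTransform(0, alpha = 0)), 0)
    expect_equal(unname(vstTransform(1, alpha = 1)), 2 * asinh(1),
                 tolerance = 1e-12)

    q <- c(0.5, 1, 7, 100, 1e4)
    limit <- vstTransform(q, alpha = 1e-8)
    expect_lt(max(abs(limit / (2 * sqrt(q)) - 1)), 1e-4)

    # strict monotonicity in q for a spread of alphas
    qs <- seq(0, 50, by = 0.5)
    for (a in c(0, 0.01, 0.05, 1))
        expect_true(all(diff(vstTransform(qs, alpha = a)) > 0))

    expect_error(vstTransform(matrix(-1), alpha = 0.1), "nonnegative")
    expect_error(vstTransform(matrix(1), alpha = -0.1), "alpha")
})

test_that("the VST stabilizes NB variance across two decades of mean", {
    alpha <- 0.05
    mus <- 10^seq(2, 4, length.out = 12)
    set.seed(5)
    sds <- vapply(mus, function(mu) {
        k <- rnbinom(300, mu = mu, size = 1 / alpha)
        sd(vstTransform(k, alpha = alpha))
    }, numeric(1))
    expect_lt(max(sds) / min(sds), 2.5)
})
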