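# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic child-seed derivation: keeps fan-out seeds distinct across
# stages while staying inside 32-bit integer range.
childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               2147483587) + 1L
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Pooled SD of observations about group means: sqrt(SS / (n - k)).
pooledSD <- function(values, groups) {
    groups <- as.factor(groups)
    m <- tapply(values, groups, mean)
    resid <- values - m[groups]
    df <- length(values) - nlevels(droplevels(groups))
    if (df <= 0) return(NA_real_)
    sqrt(sum(resid^2) / df)
}
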