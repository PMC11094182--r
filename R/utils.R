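# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# Derive a purpose-specific RNG seed from a user seed. Distinct purposes
# give decorrelated streams, so e.g. generating a cohort and splitting it
# with the same user seed never share random draws (a minimal-standards
# Lehmer step; all arithmetic stays exact in doubles).
seedStream <- function(seed, purpose) {
    chars <- utf8ToInt(purpose)
    h <- sum(chars * seq_along(chars)) %% 2147483647
    as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Stratified fold ids: within each class, samples are shuffled and dealt
# round-robin so fold class proportions match the data.
stratifiedFolds <- function(y, nFolds, seed) {
    stopifnot(nFolds >= 2)
    fold <- integer(length(y))
    withSeed(seedStream(seed, "cv-folds"), {
        for (cls in unique(y)) {
            idx <- which(y == cls)
            if (length(idx) < nFolds)
                stop("class with fewer members (", length(idx),
                     ") than folds (", nFolds, ")")
            fold[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
        }
    })
    fold
}

clampProb <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

binomialDeviance <- function(y, p) {
    p <- clampProb(p)
    -2 * (y * log(p) + (1 - y) * log(1 - p))
}

# glmnet warns when a binomial class has < 8 observations; class balance
# is already controlled by stratified splitting/folding upstream, so the
# advisory is muffled to keep resampling loops quiet.
quietGlmnet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
}
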