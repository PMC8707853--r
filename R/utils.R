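# internal helpers

# run fun() under a temporary seed, restoring the caller's RNG state;
# seed = NULL means use the ambient RNG stream untouched
.withSeed <- function(seed, fun) {
    if (is.null(seed)) return(fun())
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
        stop("seed must be a single integer or NULL")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    fun()
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# seeded near-equal partition of n items into k folds; returns fold index
.makeFolds <- function(n, k, seed = NULL) {
    if (k < 2) .stopf("need at least 2 cross-validation groups")
    if (n < k) .stopf("fewer samples (%d) than folds (%d)", n, k)
    .withSeed(seed, function() sample(rep_len(seq_len(k), n)))
}
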