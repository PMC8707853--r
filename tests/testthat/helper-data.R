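# Shared fixture builders; everything is generated in code at test time.

# the study-default configuration in its noiseless limit
noiselessConfig <- function(seed = 1L) {
    syntheticConfig(baselineOffsetSd = 0, baselineSlopeSd = 0,
                    scatterSlopeSd = 0, replicateNoiseSd = 0,
                    channelNoiseSd = 0, seed = seed)
}

# small single-cultivar configuration for cheap targeted tests
tinyConfig <- function(n = 12L, nReplicates = 2L, seed = 1L, ...) {
    cv <- defaultCultivars()[1, ]
    cv$n <- as.integer(n)
    syntheticConfig(cultivars = cv, nReplicates = nReplicates,
                    seed = seed, ...)
}

# replicate-averaged default synthetic set plus its reference table
defaultStudySet <- function(seed = 1L) {
    cfg <- syntheticConfig(seed = seed)
    refs <- generateReference(cfg)
    list(cfg = cfg, refs = refs,
         spectra = averageReplicates(generateSpectra(cfg, refs)))
}

randomSpectrumMatrix <- function(n, p, seed = 1) {
    set.seed(seed)
    matrix(rnorm(n * p, mean = 0.8, sd = 0.3), n, p)
}
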