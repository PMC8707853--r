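#' Default cultivar reference distributions
#'
#' Two cultivar populations mirroring the study design: Kennebec (n = 48)
#' and Agria (n = 41), with dry matter (%) and reducing sugars (g/100 g)
#' drawn from truncated normal distributions with the tabulated
#' mean/SD/min/max of each cultivar.
#'
#' @return data.frame with one row per cultivar.
#' @export
defaultCultivars <- function() {
    data.frame(
        label = c("Kennebec", "Agria"),
        n = c(48L, 41L),
        dmMean = c(19.88, 20.19), dmSd = c(1.63, 1.04),
        dmMin = c(16.00, 17.30), dmMax = c(22.10, 22.20),
        sugarMean = c(0.23, 0.15), sugarSd = c(0.09, 0.04),
        sugarMin = c(0.15, 0.10), sugarMax = c(0.49, 0.37),
        stringsAsFactors = FALSE)
}

#' Default constituent absorption bands
#'
#' Plausible NIR band assignments for the synthetic mixture model: water
#' (concentration 100 - dry matter) dominates with O-H overtone/combination
#' bands near 970, 1190 and 1450 nm; carbohydrate (dry matter) bands sit
#' near 1200 and 1580 nm; reducing sugars contribute weaker features near
#' 1430 and 1690 nm. Amplitudes are absorbance units per unit concentration
#' (% for dry matter/water, g/100 g for sugars). The pipeline's correctness
#' never depends on these choices; they are plain configuration.
#'
#' @return data.frame with columns `constituent`, `center`, `width`,
#'   `amplitude`.
#' @export
defaultBands <- function() {
    data.frame(
        constituent = c("water", "water", "water",
                        "dry_matter", "dry_matter",
                        "reducing_sugars", "reducing_sugars"),
        center = c(970, 1190, 1450, 1200, 1580, 1430, 1690),
        width = c(45, 50, 55, 40, 60, 30, 35),
        amplitude = c(0.004, 0.005, 0.012, 0.006, 0.008, 0.20, 0.15),
        stringsAsFactors = FALSE)
}

#' Build a synthetic study configuration
#'
#' Defaults emulate the study conditions: 89 samples (48 Kennebec + 41
#' Agria) with six replicate scans each (534 spectra) on a 900--1700 nm
#' grid at 6 nm intervals (134 channels, last channel 1698 nm), reference
#' values from the tabulated per-cultivar truncated normals, and a noise
#' model with per-sample baseline, per-replicate multiplicative scatter and
#' additive noise. See the package vignette for how the default noise
#' levels were chosen.
#'
#' @param wavelengthStart,wavelengthEnd,wavelengthStep grid in nm; channels
#'   are `start + k*step` for `k = 0, 1, ...` while `<= end`.
#' @param nReplicates replicate scans per sample.
#' @param cultivars per-cultivar reference distributions,
#'   see [defaultCultivars()].
#' @param bands constituent absorption bands, see [defaultBands()].
#' @param baselineOffsetSd,baselineSlopeSd per-sample additive baseline
#'   (absorbance; slope per nm).
#' @param scatterSlopeSd SD of the per-replicate multiplicative scatter
#'   factor (1 + slope).
#' @param replicateNoiseSd per-replicate additive offset SD (absorbance).
#' @param channelNoiseSd independent per-channel noise SD (absorbance).
#' @param seed integer seed used by the generation functions.
#' @return a validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig()
#' length(wavelengthGrid(cfg))  # 134
#' @export
syntheticConfig <- function(wavelengthStart = 900, wavelengthEnd = 1700,
                            wavelengthStep = 6, nReplicates = 6L,
                            cultivars = defaultCultivars(),
                            bands = defaultBands(),
                            baselineOffsetSd = 0.05,
                            baselineSlopeSd = 5e-5,
                            scatterSlopeSd = 0.08,
                            replicateNoiseSd = 0.01,
                            channelNoiseSd = 0.05,
                            seed = 1L) {
    new("SyntheticConfig",
        wavelengthStart = wavelengthStart, wavelengthEnd = wavelengthEnd,
        wavelengthStep = wavelengthStep, nReplicates = as.integer(nReplicates),
        cultivars = cultivars, bands = bands,
        baselineOffsetSd = baselineOffsetSd,
        baselineSlopeSd = baselineSlopeSd,
        scatterSlopeSd = scatterSlopeSd,
        replicateNoiseSd = replicateNoiseSd,
        channelNoiseSd = channelNoiseSd,
        seed = as.integer(seed))
}

#' Wavelength grid of a synthetic configuration
#'
#' Closed at the start; the end point is included only when it lies on the
#' grid (`start + k*step <= end`). The default 900--1700 nm at 6 nm gives
#' 134 channels ending at 1698 nm.
#'
#' @param config a [SyntheticConfig-class].
#' @return numeric vector of wavelengths in nm.
#' @export
wavelengthGrid <- function(config) {
    seq(config@wavelengthStart, config@wavelengthEnd,
        by = config@wavelengthStep)
}

# truncated-normal draws by rejection: resample out-of-bounds values until
# all lie in [lo, hi]; sd = 0 degenerates to the mean
.rtruncnorm <- function(n, mean, sd, lo, hi) {
    if (sd == 0) {
        if (mean < lo || mean > hi)
            .stopf("degenerate distribution: mean %g outside [%g, %g]",
                   mean, lo, hi)
        return(rep(mean, n))
    }
    x <- rnorm(n, mean, sd)
    bad <- which(x < lo | x > hi)
    guard <- 0L
    while (length(bad)) {
        x[bad] <- rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] < lo | x[bad] > hi]
        guard <- guard + 1L
        if (guard > 100000L)
            .stopf("rejection sampling failed: bounds [%g, %g] too far from mean %g (sd %g)",
                   lo, hi, mean, sd)
    }
    x
}

#' Generate a synthetic reference table
#'
#' One row per sample; each constituent is drawn from its cultivar's
#' truncated normal (resampling until in bounds, which matches the tabulated
#' min/max without distorting the mean for mild truncation).
#'
#' @param config a [SyntheticConfig-class].
#' @param seed seed for this draw; defaults to `config@seed`.
#' @return data.frame with columns `sample_id`, `cultivar`, `dry_matter`,
#'   `reducing_sugars`.
#' @examples
#' refs <- generateReference(syntheticConfig())
#' table(refs$cultivar)  # Agria 41, Kennebec 48
#' @export
generateReference <- function(config, seed = config@seed) {
    validObject(config)
    cv <- config@cultivars
    .withSeed(seed, function() {
        out <- lapply(seq_len(nrow(cv)), function(i) {
            r <- cv[i, ]
            data.frame(
                cultivar = rep(r$label, r$n),
                dry_matter = .rtruncnorm(r$n, r$dmMean, r$dmSd,
                                         r$dmMin, r$dmMax),
                reducing_sugars = .rtruncnorm(r$n, r$sugarMean, r$sugarSd,
                                              r$sugarMin, r$sugarMax),
                stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, out)
        data.frame(sample_id = sprintf("S%03d", seq_len(nrow(out))),
                   out, stringsAsFactors = FALSE)
    })
}

# concentration of a named constituent given the reference table;
# water is the complement of dry matter on a 100% basis
.constituentConcentration <- function(refs, name) {
    switch(name,
           water = 100 - refs$dry_matter,
           dry_matter = refs$dry_matter,
           reducing_sugars = refs$reducing_sugars,
           .stopf("unknown constituent '%s' in band table", name))
}

#' Generate synthetic replicate spectra
#'
#' Beer--Lambert-style mixture: each sample's latent absorbance is the sum
#' over constituents of concentration times the constituent's Gaussian band
#' profile, plus a per-sample linear baseline. Each replicate scan is the
#' latent spectrum under multiplicative scatter `(1 + slope)`, plus a
#' per-replicate offset and independent channel noise.
#'
#' @param config a [SyntheticConfig-class].
#' @param refs reference table covering all samples to simulate (one
#'   spectrum set row block per reference row).
#' @param seed seed for this draw; defaults to `config@seed + 1` so that
#'   reference and spectra generation use distinct streams.
#' @return a [SpectraSet-class] in absorbance mode with
#'   `nrow(refs) * nReplicates` spectra.
#' @examples
#' cfg <- syntheticConfig()
#' s <- generateSpectra(cfg, generateReference(cfg))
#' ncol(s)  # 534
#' @export
generateSpectra <- function(config, refs, seed = config@seed + 1L) {
    validObject(config)
    need <- c("sample_id", "dry_matter", "reducing_sugars")
    if (!all(need %in% names(refs)))
        .stopf("refs must have columns %s", paste(need, collapse = ", "))
    if (anyNA(refs[need]))
        .stopf("refs contains missing values")
    wl <- wavelengthGrid(config)
    p <- length(wl)
    n <- nrow(refs)
    r <- config@nReplicates
    bands <- config@bands
    constituents <- unique(bands$constituent)
    # channels x constituents profile matrix
    profiles <- vapply(constituents, function(cn) {
        b <- bands[bands$constituent == cn, , drop = FALSE]
        rowSums(vapply(seq_len(nrow(b)), function(j)
            b$amplitude[j] * exp(-(wl - b$center[j])^2 / (2 * b$width[j]^2)),
            numeric(p)))
    }, numeric(p))
    conc <- vapply(constituents, function(cn)
        .constituentConcentration(refs, cn), numeric(n))
    latentChem <- conc %*% t(profiles)           # n x p
    .withSeed(seed, function() {
        offsets <- rnorm(n, 0, config@baselineOffsetSd)
        slopes <- rnorm(n, 0, config@baselineSlopeSd)
        latent <- latentChem + outer(offsets, rep(1, p)) + outer(slopes, wl)
        scat <- matrix(rnorm(n * r, 0, config@scatterSlopeSd), n, r)
        repOff <- matrix(rnorm(n * r, 0, config@replicateNoiseSd), n, r)
        values <- matrix(NA_real_, n * r, p)
        for (i in seq_len(n)) {
            for (k in seq_len(r)) {
                row <- (i - 1L) * r + k
                values[row, ] <- (1 + scat[i, k]) * latent[i, ] +
                    repOff[i, k] +
                    rnorm(p, 0, config@channelNoiseSd)
            }
        }
        SpectraSet(values, wl,
                   sampleIds = rep(refs$sample_id, each = r),
                   replicateIds = rep(seq_len(r), times = n),
                   cultivar = if ("cultivar" %in% names(refs))
                       rep(refs$cultivar, each = r) else NULL,
                   mode = "absorbance")
    })
}

#' Random calibration/validation split
#'
#' Disjoint exhaustive random partition of the sample ids, by default 70
#' calibration and 19 external validation samples.
#'
#' @param ids sample identifiers.
#' @param nCal,nVal partition sizes; must sum to `length(ids)`.
#' @param seed optional seed for a reproducible split.
#' @return list with character vectors `calibration` and `validation`.
#' @export
splitCalibrationValidation <- function(ids, nCal = 70, nVal = 19,
                                       seed = NULL) {
    if (nCal + nVal != length(ids))
        .stopf("nCal + nVal (%d) must equal the number of ids (%d)",
               nCal + nVal, length(ids))
    if (nCal < 1 || nVal < 1)
        .stopf("both partitions must be non-empty")
    if (anyDuplicated(ids))
        .stopf("sample ids must be unique")
    .withSeed(seed, function() {
        cal <- sample(ids, nCal)
        list(calibration = cal, validation = setdiff(ids, cal))
    })
}
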