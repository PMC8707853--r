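#' @describeIn SpectraSet samples-by-channels numeric matrix of the spectra
#'   (rows named by spectrum, columns by wavelength).
#' @param x a `SpectraSet`
#' @export
setMethod("spectraValues", "SpectraSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "spectra"))
    rownames(m) <- sampleIds(x)
    colnames(m) <- format(wavelengths(x), trim = TRUE)
    m
})

#' @describeIn SpectraSet wavelength grid in nm.
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
    SummarizedExperiment::rowData(x)$wavelength)

#' @describeIn SpectraSet `"reflectance"` or `"absorbance"`.
#' @export
setMethod("spectraMode", "SpectraSet", function(x)
    S4Vectors::metadata(x)$mode)

#' @describeIn SpectraSet sample identifier per spectrum.
#' @export
setMethod("sampleIds", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$sample_id)

#' @describeIn SpectraSet replicate labels (NA when replicate-averaged).
#' @export
setMethod("replicateIds", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$replicate)

#' @describeIn SpectraSet cultivar label per spectrum.
#' @export
setMethod("cultivarLabels", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$cultivar)

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SpectraSet: %d spectra x %d channels (%s)\n",
                ncol(object), nrow(object), spectraMode(object)))
    cat(sprintf("  wavelengths: %g .. %g nm\n", min(wl), max(wl)))
    cat(sprintf("  samples: %d unique", length(unique(sampleIds(object)))))
    rep <- replicateIds(object)
    if (!all(is.na(rep)))
        cat(sprintf(", replicates per sample: %s",
                    paste(unique(table(sampleIds(object))), collapse = "/")))
    cat("\n")
    cu <- cultivarLabels(object)
    if (!all(is.na(cu)))
        cat("  cultivars:", paste(unique(cu), collapse = ", "), "\n")
    invisible(NULL)
})

#' Convert reflectance spectra to absorbance
#'
#' Replaces reflectance values \eqn{R} by the pseudo-absorbance
#' \eqn{\log_{10}(1/R)}, the working unit of NIR chemometrics. Requires all
#' \eqn{R \in (0, 1]}; the error names the first offending spectrum/channel.
#'
#' @param x a [SpectraSet-class] in reflectance mode.
#' @return The same set in absorbance mode.
#' @examples
#' s <- SpectraSet(matrix(c(1, 0.1), 1), c(900, 906), "a",
#'                 mode = "reflectance")
#' spectraValues(toAbsorbance(s))  # 0 and 1
#' @export
setMethod("toAbsorbance", "SpectraSet", function(x) {
    if (spectraMode(x) != "reflectance")
        .stopf("toAbsorbance() expects a reflectance-mode SpectraSet")
    v <- SummarizedExperiment::assay(x, "spectra")
    bad <- which(!(v > 0), arr.ind = TRUE)
    if (nrow(bad)) {
        .stopf("reflectance must be in (0, 1]: spectrum %d, channel %g nm has R = %g",
               bad[1, 2], wavelengths(x)[bad[1, 1]], v[bad[1, 1], bad[1, 2]])
    }
    if (any(v > 1))
        warning("reflectance values > 1 found; absorbance will be negative")
    SummarizedExperiment::assay(x, "spectra") <- -log10(v)
    S4Vectors::metadata(x)$mode <- "absorbance"
    validObject(x)
    x
})

#' Average replicate scans into one spectrum per sample
#'
#' Arithmetic mean over the replicate spectra of each sample, in absorbance
#' space. Averaging is deliberately refused in reflectance mode: by Jensen's
#' inequality \eqn{\log(1/\bar R) \ne \overline{\log(1/R)}}, so the pipeline
#' fixes the order as convert-then-average.
#'
#' @param x a [SpectraSet-class] in absorbance mode with replicate ids.
#' @return A [SpectraSet-class] with one spectrum per sample, replicate ids
#'   dropped; samples keep their first-appearance order.
#' @export
setMethod("averageReplicates", "SpectraSet", function(x) {
    if (spectraMode(x) != "absorbance")
        .stopf("averageReplicates() refuses reflectance mode: convert with toAbsorbance() first")
    rep <- replicateIds(x)
    if (all(is.na(rep)))
        .stopf("no replicate ids present; data may already be averaged")
    ids <- sampleIds(x)
    uid <- unique(ids)
    v <- spectraValues(x)
    avg <- matrix(NA_real_, length(uid), ncol(v))
    cult <- character(length(uid))
    for (i in seq_along(uid)) {
        rows <- which(ids == uid[i])
        if (!length(rows)) .stopf("sample '%s' has zero replicates", uid[i])
        avg[i, ] <- colMeans(v[rows, , drop = FALSE])
        cult[i] <- cultivarLabels(x)[rows[1]]
    }
    SpectraSet(avg, wavelengths(x), uid, replicateIds = NULL,
               cultivar = cult, mode = "absorbance")
})
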