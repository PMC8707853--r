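# Scatter corrections and the four-digit math-treatment code.
#
# All operators shrink the valid wavelength range rather than padding
# (no data is fabricated at the spectrum edges), and the SD convention is
# n - 1 throughout, matching common chemometric practice.

.asSpectraMatrix <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

.snvMatrix <- function(m) {
    if (ncol(m) < 2) .stopf("SNV needs at least 2 channels")
    out <- t(apply(m, 1, function(x) {
        s <- sd(x)
        if (!is.finite(s) || s < 1e-300)
            .stopf("degenerate spectrum: zero SD, SNV undefined")
        (x - mean(x)) / s
    }))
    dimnames(out) <- dimnames(m)
    out
}

.mscMatrix <- function(m, reference = NULL) {
    if (is.null(reference)) {
        if (nrow(m) < 2)
            .stopf("MSC needs at least 2 spectra when no reference is supplied")
        reference <- colMeans(m)
    }
    if (length(reference) != ncol(m))
        .stopf("MSC reference length (%d) does not match channel count (%d)",
               length(reference), ncol(m))
    mr <- mean(reference)
    rc <- reference - mr
    denom <- sum(rc^2)
    out <- m
    for (i in seq_len(nrow(m))) {
        x <- m[i, ]
        b <- sum(rc * (x - mean(x))) / denom
        a <- mean(x) - b * mr
        if (abs(b) < 1e-12)
            .stopf("degenerate MSC fit for spectrum %d: slope ~ 0", i)
        out[i, ] <- (x - a) / b
    }
    attr(out, "reference") <- reference
    out
}

.detrendMatrix <- function(m, wl, order = 2) {
    if (ncol(m) <= order)
        .stopf("detrend of order %d needs more than %d channels",
               order, order)
    # orthogonal polynomial basis in wavelength, intercept included
    basis <- cbind(1, stats::poly(wl, degree = order))
    fit <- lm.fit(basis, t(m))
    out <- t(as.matrix(fit$residuals))
    dimnames(out) <- dimnames(m)
    out
}

.movingAverage <- function(m, wl, s) {
    if (s <= 1) return(list(values = m, wavelengths = wl))
    p <- ncol(m)
    nOut <- p - s + 1L
    if (nOut < 2) .stopf("smoothing window %d leaves fewer than 2 channels", s)
    cs <- cbind(0, t(apply(m, 1, cumsum)))
    idx <- seq_len(nOut)
    vals <- (cs[, idx + s, drop = FALSE] - cs[, idx, drop = FALSE]) / s
    wlOut <- vapply(idx, function(i) mean(wl[i:(i + s - 1L)]), numeric(1))
    list(values = vals, wavelengths = wlOut)
}

.gapDerivative <- function(m, wl, g) {
    p <- ncol(m)
    if (p - g < 2) .stopf("gap derivative (g = %d) leaves fewer than 2 channels", g)
    idx <- seq_len(p - g)
    list(values = m[, idx + g, drop = FALSE] - m[, idx, drop = FALSE],
         wavelengths = (wl[idx + g] + wl[idx]) / 2)
}

.mathCodeMatrix <- function(m, wl, code) {
    t <- mathTreatment("none", code)   # validates the code
    d <- code[1]; g <- code[2]; s1 <- code[3]; s2 <- code[4]
    nOut <- ncol(m) - d * g - (s1 - 1) - (s2 - 1)
    if (nOut < 2)
        .stopf("math code %s leaves %d channels; need at least 2",
               paste(code, collapse = ","), nOut)
    cur <- .movingAverage(m, wl, s1)
    if (d >= 1) for (k in seq_len(d))
        cur <- .gapDerivative(cur$values, cur$wavelengths, g)
    cur <- .movingAverage(cur$values, cur$wavelengths, s2)
    cur
}

#' Standard normal variate (SNV) correction
#'
#' Per-spectrum z-scoring: each spectrum is centred to mean 0 and scaled to
#' SD 1 (denominator n - 1), removing additive offset and multiplicative
#' scatter. Invariant under affine transforms `a*x + b` (a > 0) of a
#' spectrum, and idempotent.
#'
#' @param x numeric vector (one spectrum), matrix (spectra in rows), or
#'   [SpectraSet-class] in absorbance mode.
#' @param ... unused.
#' @return object of the same kind with corrected spectra.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
setMethod("snv", "numeric", function(x, ...)
    drop(.snvMatrix(.asSpectraMatrix(x))))

#' @rdname snv-numeric-method
#' @export
setMethod("snv", "matrix", function(x, ...) .snvMatrix(x))

#' @rdname snv-numeric-method
#' @export
setMethod("snv", "SpectraSet", function(x, ...) {
    SpectraSet(.snvMatrix(spectraValues(x)), wavelengths(x), sampleIds(x),
               replicateIds(x), cultivarLabels(x), spectraMode(x))
})

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum `x` is regressed on a reference spectrum by ordinary least
#' squares over channels, `x ~ a + b * ref`, and replaced by `(x - a) / b`.
#' The reference defaults to the set's mean spectrum and is returned with
#' the result (attribute `reference` for matrices, metadata entry
#' `mscReference` for spectra sets) so that validation spectra can be
#' corrected against the calibration reference.
#'
#' @param x matrix of spectra (rows) or a [SpectraSet-class].
#' @param reference optional reference spectrum; defaults to the mean.
#' @param ... unused.
#' @return corrected object carrying the reference used.
#' @export
setMethod("msc", "matrix", function(x, reference = NULL, ...)
    .mscMatrix(x, reference))

#' @rdname msc-matrix-method
#' @export
setMethod("msc", "SpectraSet", function(x, reference = NULL, ...) {
    v <- .mscMatrix(spectraValues(x), reference)
    out <- SpectraSet(v, wavelengths(x), sampleIds(x), replicateIds(x),
                      cultivarLabels(x), spectraMode(x))
    S4Vectors::metadata(out)$mscReference <- attr(v, "reference")
    out
})

#' Detrend correction
#'
#' Subtracts the least-squares polynomial of the given order (default 2,
#' the standard detrend definition) in wavelength from each spectrum,
#' leaving the residuals. Annihilates any spectrum that is exactly a
#' polynomial of that order.
#'
#' @param x numeric vector, matrix of spectra, or [SpectraSet-class].
#' @param wavelengths channel wavelengths (vector/matrix methods only).
#' @param order polynomial order, default 2.
#' @param ... unused.
#' @return detrended object of the same kind.
#' @export
setMethod("detrendSpectra", "numeric",
          function(x, wavelengths, order = 2, ...)
    drop(.detrendMatrix(.asSpectraMatrix(x), wavelengths, order)))

#' @rdname detrendSpectra-numeric-method
#' @export
setMethod("detrendSpectra", "matrix",
          function(x, wavelengths, order = 2, ...)
    .detrendMatrix(x, wavelengths, order))

#' @rdname detrendSpectra-numeric-method
#' @export
setMethod("detrendSpectra", "SpectraSet", function(x, order = 2, ...) {
    SpectraSet(.detrendMatrix(spectraValues(x), wavelengths(x), order),
               wavelengths(x), sampleIds(x), replicateIds(x),
               cultivarLabels(x), spectraMode(x))
})

#' Apply a four-digit derivative/smoothing math code
#'
#' The code `(d, g, s1, s2)` is applied as: moving-average smoothing over
#' `s1` points, then the gap derivative `y[i] = x[i + g] - x[i]` repeated
#' `d` times (each application shortening the spectrum by `g` channels),
#' then smoothing over `s2` points. Wavelengths are relabelled as the
#' midpoint (mean) of each window, and the valid range shrinks at the
#' edges: the output has `n - d*g - (s1 - 1) - (s2 - 1)` channels. Code
#' `0,0,1,1` is the identity.
#'
#' @param x matrix of spectra or [SpectraSet-class].
#' @param code integer vector `(d, g, s1, s2)`.
#' @param wavelengths channel wavelengths (matrix method only).
#' @param ... unused.
#' @return matrix method: list with `values` and `wavelengths`;
#'   SpectraSet method: a new [SpectraSet-class] on the shrunken grid.
#' @export
setMethod("applyMathCode", "matrix", function(x, code, wavelengths, ...)
    .mathCodeMatrix(x, wavelengths, code))

#' @rdname applyMathCode-matrix-method
#' @export
setMethod("applyMathCode", "SpectraSet", function(x, code, ...) {
    res <- .mathCodeMatrix(spectraValues(x), wavelengths(x), code)
    out <- SpectraSet(res$values, res$wavelengths, sampleIds(x),
                      replicateIds(x), cultivarLabels(x), spectraMode(x))
    S4Vectors::metadata(out)$mscReference <-
        S4Vectors::metadata(x)$mscReference
    out
})

#' Construct a math treatment
#'
#' @param scatter scatter correction: `"none"`, `"snv"`, `"msc"`,
#'   `"detrend"` or `"snvdt"` (SNV followed by detrend).
#' @param code four-digit derivative/smoothing code `(d, g, s1, s2)`.
#' @return a validated [MathTreatment-class].
#' @examples
#' mathTreatment("snv", c(2, 4, 4, 1))
#' @export
mathTreatment <- function(scatter = "none", code = c(0L, 0L, 1L, 1L)) {
    new("MathTreatment", scatter = scatter, code = as.integer(code))
}

.scatterDisplay <- c(none = "None", snv = "SNV only", msc = "Standard MSC",
                     detrend = "Detrend only", snvdt = "SNV-Detrend")

#' Parse a treatment display string
#'
#' Accepts the display form used in calibration tables, e.g.
#' `"SNV only 0,0,1,1"`, `"Standard MSC 2,10,10,1"`, `"Detrend only
#' 2,8,6,1"`, `"None 2,4,4,1"`, `"SNV-Detrend 1,4,4,1"` (also `"SNV-DT"`),
#' case-insensitively.
#'
#' @param s a single string: scatter name followed by the 4-digit code.
#' @return a [MathTreatment-class].
#' @export
parseTreatment <- function(s) {
    m <- regexec("^\\s*(.*?)\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*,\\s*(\\d+)\\s*$",
                 s)
    parts <- regmatches(s, m)[[1]]
    if (length(parts) != 6)
        .stopf("cannot parse treatment string '%s'", s)
    name <- tolower(trimws(parts[2]))
    if (!nzchar(name)) name <- "none"
    scatter <- switch(name,
        "none" = "none",
        "snv" = , "snv only" = "snv",
        "msc" = , "standard msc" = "msc",
        "detrend" = , "detrend only" = , "dt" = "detrend",
        "snv-dt" = , "snv-detrend" = , "snvdt" = "snvdt",
        .stopf("unknown scatter correction '%s' in '%s'", parts[2], s))
    mathTreatment(scatter, as.integer(parts[3:6]))
}

#' Display form of a treatment
#'
#' @param t a [MathTreatment-class].
#' @return string such as `"SNV only 2,4,4,1"`.
#' @export
formatTreatment <- function(t) {
    paste(.scatterDisplay[[t@scatter]], paste(t@code, collapse = ","))
}

setMethod("show", "MathTreatment", function(object)
    cat("MathTreatment:", formatTreatment(object), "\n"))

#' Apply a full math treatment to a spectra set
#'
#' Scatter correction first (SNV-Detrend = SNV then detrend), then the
#' four-digit math code. Deterministic; the MSC reference actually used is
#' stored in the result metadata so new spectra can be treated identically.
#'
#' @param x a [SpectraSet-class] in absorbance mode.
#' @param treatment a [MathTreatment-class] or display string.
#' @param mscReference optional reference spectrum for MSC (used when
#'   treating validation spectra with a calibration model's reference).
#' @param ... unused.
#' @return treated [SpectraSet-class].
#' @export
setMethod("applyTreatment", "SpectraSet",
          function(x, treatment, mscReference = NULL, ...) {
    if (is.character(treatment)) treatment <- parseTreatment(treatment)
    validObject(treatment)
    out <- switch(treatment@scatter,
        none = x,
        snv = snv(x),
        msc = msc(x, reference = mscReference),
        detrend = detrendSpectra(x, order = 2),
        snvdt = detrendSpectra(snv(x), order = 2))
    out <- applyMathCode(out, treatment@code)
    S4Vectors::metadata(out)$treatment <- treatment
    out
})

#' Default treatment grid
#'
#' The 25-candidate grid crossing the five scatter options (none, SNV,
#' MSC, detrend, SNV-detrend) with the five math codes `0,0,1,1`,
#' `1,4,4,1`, `2,4,4,1`, `2,8,6,1` and `2,10,10,1`.
#'
#' @return list of 25 [MathTreatment-class] objects.
#' @export
defaultTreatmentGrid <- function() {
    scatters <- c("none", "snv", "msc", "detrend", "snvdt")
    codes <- list(c(0, 0, 1, 1), c(1, 4, 4, 1), c(2, 4, 4, 1),
                  c(2, 8, 6, 1), c(2, 10, 10, 1))
    out <- list()
    for (sc in scatters) for (cd in codes)
        out[[length(out) + 1L]] <- mathTreatment(sc, cd)
    out
}
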