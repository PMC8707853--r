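#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats coef cor cov lm.fit mahalanobis pt sd var kruskal.test
#'   rnorm runif predict
#' @importFrom utils head
NULL

#' SpectraSet: a set of NIR spectra with sample metadata
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' set of near-infrared spectra on a common wavelength grid. Rows of the
#' underlying assay are wavelength channels (with the wavelength in nm stored
#' in `rowData`), columns are individual spectra (replicate scans or
#' replicate-averaged samples) with `sample_id`, `replicate` and `cultivar`
#' columns in `colData`. The measurement mode -- reflectance \eqn{R} or
#' absorbance \eqn{\log_{10}(1/R)} -- is stored in the object metadata.
#'
#' Chemometric operations in this package work on the samples-by-channels
#' orientation returned by [spectraValues()].
#'
#' @slot .
#'   See [SummarizedExperiment::SummarizedExperiment] for inherited slots.
#'
#' @seealso [SpectraSet()] the constructor, [spectraValues()], [wavelengths()],
#'   [toAbsorbance()], [averageReplicates()]
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- NULL
    if (!"spectra" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'spectra' is missing")
    wl <- SummarizedExperiment::rowData(object)$wavelength
    if (is.null(wl)) {
        msg <- c(msg, "rowData column 'wavelength' is missing")
    } else {
        if (!is.numeric(wl) || anyNA(wl))
            msg <- c(msg, "wavelengths must be numeric and non-missing")
        else if (length(wl) > 1 && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    mode <- S4Vectors::metadata(object)$mode
    if (is.null(mode) || length(mode) != 1 ||
        !mode %in% c("reflectance", "absorbance"))
        msg <- c(msg, "metadata 'mode' must be 'reflectance' or 'absorbance'")
    if (is.null(SummarizedExperiment::colData(object)$sample_id))
        msg <- c(msg, "colData column 'sample_id' is missing")
    if (is.null(msg)) TRUE else msg
}
setValidity("SpectraSet", .validSpectraSet)

#' Construct a SpectraSet
#'
#' @param values numeric matrix of spectra, one row per spectrum and one
#'   column per wavelength channel.
#' @param wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing, of length `ncol(values)`.
#' @param sampleIds character vector of sample identifiers, one per spectrum.
#' @param replicateIds optional integer/character vector of replicate labels;
#'   `NULL` for replicate-averaged data.
#' @param cultivar optional character vector of cultivar labels per spectrum.
#' @param mode `"reflectance"` or `"absorbance"`.
#'
#' @return A [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(runif(6, 0.2, 0.9), 2), c(900, 906, 912),
#'                 sampleIds = c("a", "b"), mode = "reflectance")
#' wavelengths(s)
#' @export
SpectraSet <- function(values, wavelengths, sampleIds,
                       replicateIds = NULL, cultivar = NULL,
                       mode = c("absorbance", "reflectance")) {
    mode <- match.arg(mode)
    values <- as.matrix(values)
    if (ncol(values) != length(wavelengths))
        stop("ncol(values) must equal length(wavelengths)")
    if (nrow(values) != length(sampleIds))
        stop("nrow(values) must equal length(sampleIds)")
    cd <- S4Vectors::DataFrame(sample_id = as.character(sampleIds))
    cd$replicate <- if (is.null(replicateIds)) NA_integer_ else replicateIds
    cd$cultivar <- if (is.null(cultivar)) NA_character_ else as.character(cultivar)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(spectra = t(unname(values))),
        rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
        colData = cd)
    S4Vectors::metadata(se)$mode <- mode
    new("SpectraSet", se)
}

#' Math treatment descriptor
#'
#' A scatter-correction choice plus the four-digit derivative code
#' \eqn{(d, g, s_1, s_2)}: derivative order, derivative gap in channels,
#' first smoothing window, second smoothing window (window of 1 means no
#' smoothing). The code `0,0,1,1` leaves the spectrum untouched.
#'
#' @slot scatter one of `"none"`, `"snv"`, `"msc"`, `"detrend"`, `"snvdt"`.
#' @slot code integer vector of length 4.
#' @seealso [mathTreatment()], [parseTreatment()], [applyTreatment()]
#' @exportClass MathTreatment
setClass("MathTreatment",
         representation(scatter = "character", code = "integer"))

setValidity("MathTreatment", function(object) {
    msg <- NULL
    if (length(object@scatter) != 1 ||
        !object@scatter %in% c("none", "snv", "msc", "detrend", "snvdt"))
        msg <- c(msg, "scatter must be one of none/snv/msc/detrend/snvdt")
    code <- object@code
    if (length(code) != 4 || anyNA(code) || any(code < 0))
        msg <- c(msg, "code must be 4 non-negative integers")
    else {
        if (code[1] >= 1 && code[2] < 1)
            msg <- c(msg, "a derivative (d >= 1) requires a gap g >= 1")
        if (code[3] < 1 || code[4] < 1)
            msg <- c(msg, "smoothing windows must be >= 1 (1 = none)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Fitted modified-PLS calibration model
#'
#' Holds everything needed to replay the MPLS fit recursion on new spectra:
#' the centering vectors, per-factor weights, loadings, score regression
#' coefficients and residual-standardization scalings, together with the
#' pretreatment descriptor (including the stored MSC reference spectrum, so
#' validation spectra are corrected against the calibration reference).
#'
#' @slot xCenter,yCenter training means removed before factor extraction.
#' @slot weights,loadings channels x factors matrices.
#' @slot yLoadings per-factor score regression coefficients.
#' @slot scalings channels x factors matrix of residual-SD scalings
#'   (all 1 when `standardized` is `FALSE`).
#' @slot nFactorsMax,nFactorsSelected factor counts (selected is set by
#'   cross-validation).
#' @slot standardized whether per-factor residual standardization was on.
#' @slot earlyStopped `TRUE` when rank deficiency stopped extraction before
#'   `nFactorsMax` factors.
#' @slot fittedValues training-set predictions, one column per factor count.
#' @slot y training reference values.
#' @slot sampleIds,constituent,treatment,mscReference,wavelengths training
#'   provenance.
#' @seealso [mplsFit()], [predict,MPLSModel-method]
#' @exportClass MPLSModel
setClass("MPLSModel", representation(
    xCenter = "numeric", yCenter = "numeric",
    weights = "matrix", loadings = "matrix",
    yLoadings = "numeric", scalings = "matrix",
    nFactorsMax = "integer", nFactorsSelected = "integer",
    standardized = "logical", earlyStopped = "logical",
    fittedValues = "matrix", y = "numeric",
    sampleIds = "character", constituent = "character",
    treatment = "MathTreatment", mscReference = "numeric",
    wavelengths = "numeric"))

setValidity("MPLSModel", function(object) {
    msg <- NULL
    nf <- ncol(object@weights)
    if (ncol(object@loadings) != nf || ncol(object@scalings) != nf ||
        length(object@yLoadings) != nf)
        msg <- c(msg, "per-factor slots must have equal factor counts")
    if (nf != object@nFactorsMax)
        msg <- c(msg, "nFactorsMax must equal the stored factor count")
    if (any(object@scalings <= 0))
        msg <- c(msg, "scaling vectors must be strictly positive")
    if (object@nFactorsSelected > object@nFactorsMax ||
        object@nFactorsSelected < 0)
        msg <- c(msg, "nFactorsSelected must be in [0, nFactorsMax]")
    if (is.null(msg)) TRUE else msg
})

#' Calibration result for one math treatment
#'
#' The statistics block of one row of a calibration ranking table: retained
#' sample count after outlier elimination, reference mean/SD, applicability
#' range, SEC, RSQ, SECV and RPD, plus the fitted [MPLSModel-class], the
#' cross-validated predictions and the outlier report.
#'
#' @slot constituent constituent name.
#' @slot treatment the [MathTreatment-class] used.
#' @slot model fitted [MPLSModel-class] on the retained samples.
#' @slot statistics named numeric vector: `n`, `mean`, `sd`, `min`, `max`,
#'   `sec`, `rsq`, `secv`, `rpd`, `nFactors`.
#' @slot retainedIds sample ids kept after outlier removal.
#' @slot outlierReport data.frame with columns `pass`, `criterion`,
#'   `sample_id`, `value` for every removal.
#' @slot cvPredictions cross-validated predictions at the selected factor
#'   count, aligned with `retainedIds`.
#' @slot secvPerFactor SECV at every candidate factor count.
#' @exportClass CalibrationResult
setClass("CalibrationResult", representation(
    constituent = "character", treatment = "MathTreatment",
    model = "MPLSModel", statistics = "numeric",
    retainedIds = "character", outlierReport = "data.frame",
    cvPredictions = "numeric", secvPerFactor = "numeric"))

#' Ranked grid of calibration results
#'
#' Result of [gridSearch()]: one [CalibrationResult-class] per candidate
#' treatment, ranked by ascending SECV with ties broken by descending RSQ,
#' plus the rendered ranking table.
#'
#' @slot constituent constituent name.
#' @slot results list of [CalibrationResult-class], best first.
#' @slot table the ranking as a data.frame (treatment, N, mean, SD, range,
#'   SEC, RSQ, SECV, RPD, factors).
#' @exportClass CalibrationGrid
setClass("CalibrationGrid", representation(
    constituent = "character", results = "list", table = "data.frame"))

#' External validation statistics
#'
#' Comparison of NIR-predicted against reference values on an independent
#' validation set: bias, mean residual, RMSE (= SEP, uncorrected, denominator
#' n), bias-corrected SEP(C) (denominator n - 1), and the paired Student
#' t-test of reference vs predicted.
#'
#' @slot n validation set size.
#' @slot bias mean signed residual (reference - predicted).
#' @slot meanResidual mean absolute residual.
#' @slot meanSignedResidual mean signed residual (equals `bias`).
#' @slot rmse,sep root mean square error, denominator n (identical).
#' @slot sepC standard error of prediction corrected for bias.
#' @slot tStatistic,df,pValue paired t-test of the residuals.
#' @slot noDifference `TRUE` when p > 0.05: reference and NIR values are
#'   statistically indistinguishable.
#' @seealso [externalValidate()]
#' @exportClass ValidationResult
setClass("ValidationResult", representation(
    n = "integer", bias = "numeric", meanResidual = "numeric",
    meanSignedResidual = "numeric", rmse = "numeric", sep = "numeric",
    sepC = "numeric", tStatistic = "numeric", df = "numeric",
    pValue = "numeric", noDifference = "logical"))

#' Synthetic study configuration
#'
#' Parameters of the synthetic spectra generator: the wavelength grid, the
#' per-cultivar reference-value distributions (truncated normals), the
#' Gaussian absorption bands assigned to each constituent, and the noise
#' model (per-sample baseline offset/slope, per-replicate multiplicative
#' scatter, replicate offset noise and independent channel noise).
#'
#' @slot wavelengthStart,wavelengthEnd,wavelengthStep grid in nm; channels
#'   are `start + k * step` while `<= end`.
#' @slot nReplicates replicate scans per sample.
#' @slot cultivars data.frame with columns `label`, `n`, `dmMean`, `dmSd`,
#'   `dmMin`, `dmMax`, `sugarMean`, `sugarSd`, `sugarMin`, `sugarMax`.
#' @slot bands data.frame with columns `constituent`, `center` (nm),
#'   `width` (nm, Gaussian sigma), `amplitude` (absorbance per unit
#'   concentration).
#' @slot baselineOffsetSd,baselineSlopeSd per-sample additive baseline.
#' @slot scatterSlopeSd per-replicate multiplicative scatter SD.
#' @slot replicateNoiseSd per-replicate additive offset SD.
#' @slot channelNoiseSd independent per-channel noise SD.
#' @slot seed integer seed for reproducible generation.
#' @seealso [syntheticConfig()], [generateReference()], [generateSpectra()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig", representation(
    wavelengthStart = "numeric", wavelengthEnd = "numeric",
    wavelengthStep = "numeric", nReplicates = "integer",
    cultivars = "data.frame", bands = "data.frame",
    baselineOffsetSd = "numeric", baselineSlopeSd = "numeric",
    scatterSlopeSd = "numeric", replicateNoiseSd = "numeric",
    channelNoiseSd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    wl <- wavelengthGrid(object)
    if (length(wl) < 2)
        msg <- c(msg, "wavelength grid must have at least 2 channels")
    cv <- object@cultivars
    need <- c("label", "n", "dmMean", "dmSd", "dmMin", "dmMax",
              "sugarMean", "sugarSd", "sugarMin", "sugarMax")
    if (!all(need %in% names(cv))) {
        msg <- c(msg, "cultivars is missing required columns")
    } else {
        if (any(cv$dmSd < 0) || any(cv$sugarSd < 0))
            msg <- c(msg, "all SDs must be >= 0")
        if (any(cv$dmMin >= cv$dmMax) || any(cv$sugarMin >= cv$sugarMax))
            msg <- c(msg, "truncation bounds must satisfy min < max")
        if (any(cv$n < 1)) msg <- c(msg, "cultivar n must be >= 1")
    }
    bd <- object@bands
    if (!all(c("constituent", "center", "width", "amplitude") %in% names(bd)))
        msg <- c(msg, "bands is missing required columns")
    else {
        if (any(bd$width <= 0)) msg <- c(msg, "band widths must be > 0")
        if (any(!is.finite(bd$amplitude)))
            msg <- c(msg, "band amplitudes must be finite")
    }
    sds <- c(object@baselineOffsetSd, object@baselineSlopeSd,
             object@scatterSlopeSd, object@replicateNoiseSd,
             object@channelNoiseSd)
    if (any(sds < 0)) msg <- c(msg, "noise SDs must be >= 0")
    if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
    if (is.null(msg)) TRUE else msg
})
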