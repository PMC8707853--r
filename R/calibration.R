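# Calibration procedure: GH/T outlier elimination, six-subset
# cross-validation with factor selection, calibration statistics and the
# treatment grid search.

#' Outlier elimination configuration
#'
#' @param hThreshold GH (global Mahalanobis) threshold; samples with
#'   GH above it are removed for spectral reasons. Default 3.
#' @param tThreshold standardized chemical residual threshold; samples
#'   with `T = |y - yhat_cv| / SECV` at or above it are removed. Default 2.5.
#' @param maxPasses maximum remove-and-refit passes (default 2, which
#'   prevents unbounded trimming).
#' @return a validated list of class `OutlierConfig`.
#' @export
outlierConfig <- function(hThreshold = 3, tThreshold = 2.5, maxPasses = 2L) {
    if (hThreshold <= 0 || tThreshold <= 0)
        .stopf("outlier thresholds must be > 0")
    if (maxPasses < 1) .stopf("maxPasses must be >= 1")
    structure(list(hThreshold = hThreshold, tThreshold = tThreshold,
                   maxPasses = as.integer(maxPasses)),
              class = "OutlierConfig")
}

#' Global Mahalanobis (GH) distances in PCA score space
#'
#' Squared Mahalanobis distance of each sample in the retained score
#' space, computed with the scores' own covariance and divided by the
#' number of components -- the "global H" convention, under which the mean
#' GH over the calibration set is `(n - 1) / n`, about 1. GH above 3 flags
#' a spectral outlier.
#'
#' @param scores score matrix (samples in rows), e.g. from
#'   [pcaDescribe()].
#' @param nComponents number of leading score columns to use.
#' @return numeric vector of GH values.
#' @export
ghDistances <- function(scores, nComponents) {
    scores <- as.matrix(scores)
    if (nComponents < 1) .stopf("nComponents must be >= 1")
    if (nrow(scores) <= nComponents)
        .stopf("need more samples than components for the score covariance")
    S <- scores[, seq_len(nComponents), drop = FALSE]
    cv <- cov(S)
    d2 <- tryCatch(mahalanobis(S, colMeans(S), cv),
                   error = function(e)
                       .stopf("singular score covariance; try fewer components"))
    d2 / nComponents
}

#' Remove spectral (GH) and chemical (T) outliers
#'
#' Per pass: GH distances are computed on the current set in the PCA
#' score space retaining the configured explained-variance target, and
#' samples with GH above `hThreshold` are dropped; then the model is
#' cross-validated on the remainder and samples whose standardized
#' held-out residual `T = |y - yhat_cv| / SECV` reaches `tThreshold` are
#' dropped. Passes repeat until no removal or `maxPasses`. Every removal
#' is reported with its criterion and value.
#'
#' When further removal would leave fewer than `nFactors + 2` samples the
#' procedure stops and flags the report as aborted rather than trimming
#' below a fittable size.
#'
#' @param X pretreated spectral matrix, samples in rows.
#' @param y reference values aligned with the rows of `X`.
#' @param config an [outlierConfig()].
#' @param nFactorsMax,cvGroups,standardizeResiduals passed to
#'   [crossValidate()].
#' @param varianceTarget PCA explained-variance target for the GH space.
#' @param seed seed for the cross-validation fold assignment.
#' @return list with `X`, `y` (retained data), `retained` (ids), `report`
#'   (data.frame: pass, criterion, sample_id, value) and `aborted`.
#' @export
removeOutliers <- function(X, y, config = outlierConfig(),
                           nFactorsMax = 16L, cvGroups = 6L,
                           standardizeResiduals = TRUE,
                           varianceTarget = 0.996, seed = NULL) {
    X <- as.matrix(X)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
    keep <- seq_len(nrow(X))
    report <- data.frame(pass = integer(0), criterion = character(0),
                         sample_id = character(0), value = numeric(0),
                         stringsAsFactors = FALSE)
    aborted <- FALSE
    minKeep <- function(nCur) max(cvGroups, min(nFactorsMax, nCur %/% 3) + 2)
    for (pass in seq_len(config$maxPasses)) {
        removedThisPass <- 0L
        # spectral criterion
        pca <- pcaDescribe(X[keep, , drop = FALSE], varianceTarget)
        gh <- ghDistances(pca$scores, pca$nComponents)
        drop <- which(gh > config$hThreshold)
        if (length(drop)) {
            if (length(keep) - length(drop) < minKeep(length(keep))) {
                aborted <- TRUE
                break
            }
            report <- rbind(report, data.frame(
                pass = pass, criterion = "GH",
                sample_id = ids[keep[drop]], value = gh[drop],
                stringsAsFactors = FALSE))
            keep <- keep[-drop]
            removedThisPass <- removedThisPass + length(drop)
        }
        # chemical criterion
        cv <- crossValidate(X[keep, , drop = FALSE], y[keep],
                            nGroups = cvGroups, nFactorsMax = nFactorsMax,
                            standardizeResiduals = standardizeResiduals,
                            seed = seed)
        secv <- cv$secv[cv$nFactors]
        resid <- abs(y[keep] - cv$cvPredictions[, cv$nFactors])
        # SECV at machine-precision level means a numerically perfect
        # model; standardized residuals are then ratios of rounding noise,
        # so the chemical criterion is switched off rather than amplified
        tval <- if (secv < 1e-8 * max(1e-8, sd(y[keep])))
                    rep(0, length(resid))
                else resid / secv
        drop <- which(tval >= config$tThreshold)
        if (length(drop)) {
            if (length(keep) - length(drop) < minKeep(length(keep))) {
                aborted <- TRUE
                break
            }
            report <- rbind(report, data.frame(
                pass = pass, criterion = "T",
                sample_id = ids[keep[drop]], value = tval[drop],
                stringsAsFactors = FALSE))
            keep <- keep[-drop]
            removedThisPass <- removedThisPass + length(drop)
        }
        if (removedThisPass == 0L) break
    }
    list(X = X[keep, , drop = FALSE], y = y[keep], retained = ids[keep],
         report = report, aborted = aborted)
}

#' Cross-validate an MPLS calibration
#'
#' Seeded random partition into `nGroups` near-equal subsets; for each
#' fold the model is fitted on the remaining folds and the held-out fold
#' is predicted at every factor count. `SECV(k)` is the root mean square
#' held-out residual (denominator n). The selected factor count minimizes
#' SECV, with ties -- including near-ties within a relative `1e-8`, which
#' absorbs floating-point jitter on noiseless data -- resolved toward
#' fewer factors.
#'
#' @param X pretreated spectral matrix, samples in rows.
#' @param y reference values.
#' @param nGroups number of cross-validation subsets (default 6).
#' @param nFactorsMax maximum factor count to evaluate.
#' @param standardizeResiduals passed to [mplsFit()].
#' @param seed seed for the fold assignment (`NULL`: ambient RNG).
#' @param folds optional explicit fold assignment (overrides the seed).
#' @return list with `secv` (per factor count), `nFactors` (selected),
#'   `cvPredictions` (samples x factor counts) and `folds`.
#' @export
crossValidate <- function(X, y, nGroups = 6L, nFactorsMax = 16L,
                          standardizeResiduals = TRUE, seed = NULL,
                          folds = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (length(y) != n) .stopf("length(y) must equal nrow(X)")
    if (is.null(folds)) folds <- .makeFolds(n, nGroups, seed)
    if (length(folds) != n) .stopf("folds must assign every sample")
    if (min(table(folds)) < 1) .stopf("every fold must be non-empty")
    nTrainMin <- n - max(table(folds))
    nf <- min(as.integer(nFactorsMax), max(1L, nTrainMin %/% 3L), ncol(X))
    preds <- matrix(NA_real_, n, nf)
    for (g in sort(unique(folds))) {
        hold <- which(folds == g)
        fit <- mplsFit(X[-hold, , drop = FALSE], y[-hold],
                       nFactorsMax = nf,
                       standardizeResiduals = standardizeResiduals)
        for (k in seq_len(nf))
            preds[hold, k] <- predict(fit, X[hold, , drop = FALSE],
                                      nFactors = k)
    }
    secv <- sqrt(colSums((y - preds)^2) / n)
    best <- min(secv)
    chosen <- which(secv <= best * (1 + 1e-8))[1]
    list(secv = secv, nFactors = chosen,
         cvPredictions = preds, folds = folds)
}

#' Calibration statistics block
#'
#' \itemize{
#'   \item `sec = sqrt(sum((y - yfit)^2) / (n - nFactors - 1))`
#'   \item `rsq`: squared Pearson correlation of reference and fitted
#'   \item `secv = sqrt(sum((y - ycv)^2) / n)`
#'   \item `sd`: sample SD of the reference values (n - 1)
#'   \item `rpd = sd / secv` (`Inf` when SECV is 0)
#'   \item applicability range: mean +/- 3 SD, with the observed extremes
#'     also reported
#' }
#'
#' @param yRef reference values of the retained calibration samples.
#' @param yFit fitted (training) predictions.
#' @param yCv cross-validated (held-out) predictions.
#' @param nFactors factor count used, consumed by the SEC denominator.
#' @return named numeric vector: `n`, `mean`, `sd`, `min`, `max`,
#'   `rangeLow`, `rangeHigh`, `sec`, `rsq`, `secv`, `rpd`, `nFactors`.
#' @export
calibrationStats <- function(yRef, yFit, yCv, nFactors) {
    n <- length(yRef)
    if (length(yFit) != n || length(yCv) != n)
        .stopf("yRef, yFit and yCv must have equal length")
    if (n <= nFactors + 1)
        .stopf("need more than nFactors + 1 samples")
    sdy <- sd(yRef)
    if (sdy < 1e-300) .stopf("zero variance in reference values")
    sec <- sqrt(sum((yRef - yFit)^2) / (n - nFactors - 1))
    rsq <- if (sd(yFit) < 1e-300) 0 else cor(yRef, yFit)^2
    secv <- sqrt(sum((yRef - yCv)^2) / n)
    rpd <- if (secv == 0) Inf else sdy / secv
    m <- mean(yRef)
    c(n = n, mean = m, sd = sdy, min = min(yRef), max = max(yRef),
      rangeLow = m - 3 * sdy, rangeHigh = m + 3 * sdy,
      sec = sec, rsq = rsq, secv = secv, rpd = rpd, nFactors = nFactors)
}

.calibrateOne <- function(X, y, treatmentObj, constituent, outlierCfg,
                          nGroups, nFactorsMax, standardizeResiduals,
                          varianceTarget, seed, mscReference = NULL,
                          wavelengths = numeric(0)) {
    out <- removeOutliers(X, y, outlierCfg, nFactorsMax = nFactorsMax,
                          cvGroups = nGroups,
                          standardizeResiduals = standardizeResiduals,
                          varianceTarget = varianceTarget, seed = seed)
    cv <- crossValidate(out$X, out$y, nGroups = nGroups,
                        nFactorsMax = nFactorsMax,
                        standardizeResiduals = standardizeResiduals,
                        seed = seed)
    k <- cv$nFactors
    fit <- mplsFit(out$X, out$y, nFactorsMax = nFactorsMax,
                   standardizeResiduals = standardizeResiduals,
                   constituent = constituent, treatment = treatmentObj,
                   mscReference = if (is.null(mscReference)) numeric(0)
                                  else mscReference,
                   wavelengths = wavelengths)
    kUse <- min(k, fit@nFactorsMax)
    fit@nFactorsSelected <- as.integer(kUse)
    stats <- calibrationStats(out$y, fit@fittedValues[, kUse],
                              cv$cvPredictions[, k], kUse)
    new("CalibrationResult", constituent = constituent,
        treatment = treatmentObj, model = fit, statistics = stats,
        retainedIds = out$retained, outlierReport = out$report,
        cvPredictions = cv$cvPredictions[, k], secvPerFactor = cv$secv)
}

#' Grid search over math treatments
#'
#' Runs the full calibration procedure -- outlier elimination,
#' cross-validation with factor selection, calibration statistics -- for
#' every candidate treatment, and ranks the results by ascending SECV,
#' ties broken by descending RSQ, then by declaration order. The optimal
#' calibration is the first element.
#'
#' @param spectra a [SpectraSet-class] in absorbance mode; replicate scans
#'   are averaged automatically.
#' @param reference reference data.frame with `sample_id` and the
#'   constituent column.
#' @param constituent constituent to calibrate (e.g. `"dry_matter"`).
#' @param treatments list of [MathTreatment-class] (or display strings);
#'   default [defaultTreatmentGrid()].
#' @param config an [outlierConfig()].
#' @param nGroups cross-validation subsets (default 6).
#' @param nFactorsMax maximum MPLS factors.
#' @param standardizeResiduals passed to [mplsFit()].
#' @param varianceTarget PCA target for the GH score space.
#' @param seed seed controlling fold assignment (shared by all candidate
#'   treatments so rankings compare like with like).
#' @return a [CalibrationGrid-class].
#' @export
gridSearch <- function(spectra, reference, constituent,
                       treatments = defaultTreatmentGrid(),
                       config = outlierConfig(), nGroups = 6L,
                       nFactorsMax = 16L, standardizeResiduals = TRUE,
                       varianceTarget = 0.996, seed = NULL) {
    if (!length(treatments)) .stopf("treatment list must be non-empty")
    if (spectraMode(spectra) != "absorbance")
        .stopf("calibration expects absorbance spectra")
    if (!all(is.na(replicateIds(spectra))))
        spectra <- averageReplicates(spectra)
    y <- alignReference(spectra, reference, constituent)
    failures <- character(0)
    results <- list()
    for (i in seq_along(treatments)) {
        tr <- treatments[[i]]
        if (is.character(tr)) tr <- parseTreatment(tr)
        res <- tryCatch({
            treated <- applyTreatment(spectra, tr)
            X <- spectraValues(treated)
            .calibrateOne(X, y, tr, constituent, config, nGroups,
                          nFactorsMax, standardizeResiduals, varianceTarget,
                          seed,
                          mscReference = S4Vectors::metadata(treated)$mscReference,
                          wavelengths = wavelengths(treated))
        }, error = function(e) e)
        if (inherits(res, "error"))
            failures <- c(failures, sprintf("%s: %s", formatTreatment(tr),
                                            conditionMessage(res)))
        else results[[length(results) + 1L]] <- res
    }
    if (!length(results))
        .stopf("all treatments failed:\n%s", paste(failures, collapse = "\n"))
    secv <- vapply(results, function(r) r@statistics[["secv"]], numeric(1))
    rsq <- vapply(results, function(r) r@statistics[["rsq"]], numeric(1))
    ord <- order(secv, -rsq, seq_along(results))
    results <- results[ord]
    new("CalibrationGrid", constituent = constituent, results = results,
        table = calibrationTable(results))
}

#' Render calibration results as a ranking table
#'
#' @param results list of [CalibrationResult-class] (e.g. the `results`
#'   of a [CalibrationGrid-class]), in rank order.
#' @return data.frame with columns mirroring a calibration report:
#'   constituent, math treatment, N, mean, SD, range min/max, SEC, RSQ,
#'   SECV, RPD and the factor count.
#' @export
calibrationTable <- function(results) {
    do.call(rbind, lapply(results, function(r) {
        s <- r@statistics
        data.frame(
            constituent = r@constituent,
            math_treatment = formatTreatment(r@treatment),
            n = unname(s["n"]), mean = unname(s["mean"]),
            sd = unname(s["sd"]),
            range_min = unname(s["rangeLow"]),
            range_max = unname(s["rangeHigh"]),
            sec = unname(s["sec"]), rsq = unname(s["rsq"]),
            secv = unname(s["secv"]), rpd = unname(s["rpd"]),
            n_factors = unname(s["nFactors"]),
            n_outliers = nrow(r@outlierReport),
            stringsAsFactors = FALSE)
    }))
}

setMethod("show", "CalibrationResult", function(object) {
    s <- object@statistics
    cat(sprintf("CalibrationResult (%s), treatment %s\n",
                object@constituent, formatTreatment(object@treatment)))
    cat(sprintf("  N = %d (after %d outlier removals), factors = %d\n",
                as.integer(s["n"]), nrow(object@outlierReport),
                as.integer(s["nFactors"])))
    cat(sprintf("  SEC = %.4g  RSQ = %.3f  SECV = %.4g  RPD = %.3f\n",
                s["sec"], s["rsq"], s["secv"], s["rpd"]))
    invisible(NULL)
})

setMethod("show", "CalibrationGrid", function(object) {
    cat(sprintf("CalibrationGrid (%s): %d treatments ranked by SECV\n",
                object@constituent, length(object@results)))
    print(utils::head(object@table, 5), digits = 4)
    if (length(object@results) > 5)
        cat(sprintf("  ... and %d more\n", length(object@results) - 5L))
    invisible(NULL)
})

#' Best calibration of a grid
#'
#' @param grid a [CalibrationGrid-class].
#' @return the rank-1 [CalibrationResult-class].
#' @export
bestCalibration <- function(grid) {
    stopifnot(is(grid, "CalibrationGrid"))
    grid@results[[1]]
}

#' Predict a constituent for new spectra from a calibration result
#'
#' Applies the calibration's math treatment to the new spectra -- using
#' the stored calibration MSC reference, not one recomputed from the new
#' set -- then predicts with the fitted MPLS model at its selected factor
#' count.
#'
#' @param object a [CalibrationResult-class].
#' @param newdata a [SpectraSet-class] in absorbance mode (replicates are
#'   averaged) or an already-pretreated numeric matrix.
#' @param nFactors optional factor-count override.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
setMethod("predict", "CalibrationResult",
          function(object, newdata,
                   nFactors = object@model@nFactorsSelected, ...) {
    if (is(newdata, "SpectraSet")) {
        if (spectraMode(newdata) != "absorbance")
            .stopf("prediction expects absorbance spectra")
        if (!all(is.na(replicateIds(newdata))))
            newdata <- averageReplicates(newdata)
        ref <- object@model@mscReference
        treated <- applyTreatment(newdata, object@treatment,
                                  mscReference = if (length(ref)) ref
                                                 else NULL)
        X <- spectraValues(treated)
    } else {
        X <- as.matrix(newdata)
    }
    p <- predict(object@model, X, nFactors = nFactors)
    names(p) <- rownames(X)
    p
})
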