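# Modified partial least squares (MPLS): PLS1 in which, after extracting
# each factor, the spectral residuals at each wavelength are divided by
# their standard deviation before the next factor is computed. With the
# standardization switched off the recursion is exactly NIPALS PLS1.

#' Fit a modified-PLS (MPLS) calibration
#'
#' PLS1 on mean-centred data. Per factor: weight `w` proportional to
#' `X'y` (unit norm), scores `t = Xw`, loading `p = X't/(t't)`, score
#' regression `q = y't/(t't)`, then deflation `X <- X - t p'`,
#' `y <- y - q t`. When `standardizeResiduals` is on, every column of the
#' deflated `X` is then divided by its residual SD (columns with SD below
#' `1e-12` keep scale 1), and the scaling vector is recorded so prediction
#' can replay centring, deflation and scaling in sequence. `y` is centred
#' but never variance-scaled; standardization enters only through the
#' per-factor residual scaling.
#'
#' The requested factor count is capped at `floor(n/3)` (and at the channel
#' count); rank deficiency (a zero-norm weight) stops extraction early and
#' is flagged in the model.
#'
#' @param X numeric matrix of pretreated absorbance, samples in rows.
#' @param y reference constituent values, one per row of `X`.
#' @param nFactorsMax maximum number of factors to extract (default 16).
#' @param standardizeResiduals logical, the "modified" in MPLS.
#' @param constituent optional constituent name stored with the model.
#' @param treatment optional [MathTreatment-class] stored with the model.
#' @param mscReference optional MSC reference spectrum stored with the
#'   model (needed to pretreat prediction spectra identically).
#' @param wavelengths optional wavelength grid of the columns of `X`.
#' @return an [MPLSModel-class].
#' @seealso [predict,MPLSModel-method], [crossValidate()]
#' @export
mplsFit <- function(X, y, nFactorsMax = 16L, standardizeResiduals = TRUE,
                    constituent = NA_character_, treatment = mathTreatment(),
                    mscReference = numeric(0), wavelengths = numeric(0)) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) .stopf("length(y) must equal nrow(X)")
    if (anyNA(X) || anyNA(y)) .stopf("missing values are not allowed")
    nf <- min(as.integer(nFactorsMax), max(1L, n %/% 3L), p)
    if (n < nf + 2) .stopf("need at least nFactors + 2 samples (%d < %d)",
                           n, nf + 2)
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(n))

    xc <- colMeans(X)
    yc <- mean(y)
    Xw <- sweep(X, 2, xc)
    yw <- y - yc
    W <- P <- S <- matrix(NA_real_, p, nf)
    q <- numeric(nf)
    fitted <- matrix(NA_real_, n, nf)
    acc <- rep(yc, n)
    actual <- 0L
    for (f in seq_len(nf)) {
        w <- drop(crossprod(Xw, yw))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) break
        w <- w / nw
        t <- drop(Xw %*% w)
        tt <- sum(t^2)
        if (tt < 1e-24) break
        pv <- drop(crossprod(Xw, t)) / tt
        qf <- sum(yw * t) / tt
        Xw <- Xw - tcrossprod(t, pv)
        yw <- yw - qf * t
        if (standardizeResiduals) {
            s <- apply(Xw, 2, sd)
            s[!is.finite(s) | s < 1e-12] <- 1
            Xw <- sweep(Xw, 2, s, "/")
        } else {
            s <- rep(1, p)
        }
        W[, f] <- w; P[, f] <- pv; S[, f] <- s; q[f] <- qf
        acc <- acc + qf * t
        fitted[, f] <- acc
        actual <- f
    }
    early <- actual < nf
    if (actual == 0L)
        .stopf("X has no correlation structure with y: zero-norm first weight")
    if (early) {
        W <- W[, seq_len(actual), drop = FALSE]
        P <- P[, seq_len(actual), drop = FALSE]
        S <- S[, seq_len(actual), drop = FALSE]
        q <- q[seq_len(actual)]
        fitted <- fitted[, seq_len(actual), drop = FALSE]
    }
    new("MPLSModel", xCenter = xc, yCenter = yc, weights = W, loadings = P,
        yLoadings = q, scalings = S, nFactorsMax = actual,
        nFactorsSelected = actual, standardized = standardizeResiduals,
        earlyStopped = early, fittedValues = fitted, y = as.numeric(y),
        sampleIds = ids, constituent = constituent, treatment = treatment,
        mscReference = as.numeric(mscReference),
        wavelengths = as.numeric(wavelengths))
}

#' Predict from an MPLS model
#'
#' Replays the fit recursion on new spectra: centring, per-factor score
#' projection, deflation and residual scaling, exactly as during fitting.
#' With `nFactors = 0` every prediction equals the calibration mean of `y`.
#'
#' @param object an [MPLSModel-class].
#' @param newdata matrix of spectra pretreated identically to the training
#'   data (same treatment and MSC reference), samples in rows.
#' @param nFactors number of factors to use; defaults to the selected
#'   count, and is capped at the number actually extracted.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "MPLSModel",
          function(object, newdata, nFactors = object@nFactorsSelected, ...) {
    newdata <- .asSpectraMatrix(newdata)
    if (ncol(newdata) != length(object@xCenter))
        .stopf("channel count mismatch: model has %d, newdata has %d",
               length(object@xCenter), ncol(newdata))
    k <- min(as.integer(nFactors), object@nFactorsMax)
    yhat <- rep(object@yCenter, nrow(newdata))
    if (k < 1) return(yhat)
    Xw <- sweep(newdata, 2, object@xCenter)
    for (f in seq_len(k)) {
        t <- drop(Xw %*% object@weights[, f])
        yhat <- yhat + object@yLoadings[f] * t
        if (f < k) {
            Xw <- Xw - tcrossprod(t, object@loadings[, f])
            Xw <- sweep(Xw, 2, object@scalings[, f], "/")
        }
    }
    yhat
})

setMethod("show", "MPLSModel", function(object) {
    cat(sprintf("MPLSModel (%s): %d factors extracted, %d selected\n",
                if (is.na(object@constituent)) "unnamed constituent"
                else object@constituent,
                object@nFactorsMax, object@nFactorsSelected))
    cat(sprintf("  channels: %d, training samples: %d\n",
                length(object@xCenter), length(object@y)))
    cat(sprintf("  treatment: %s, residual standardization: %s%s\n",
                formatTreatment(object@treatment),
                if (object@standardized) "on" else "off",
                if (object@earlyStopped) " (early stop: rank deficiency)"
                else ""))
    invisible(NULL)
})

#' PCA description of a spectral matrix
#'
#' Mean-centred singular value decomposition. The component count is the
#' smallest `k` whose cumulative explained variance reaches the target
#' (default 99.6%), the convention used to define the score space for
#' spectral outlier screening.
#'
#' @param X numeric matrix, samples in rows.
#' @param varianceTarget cumulative explained-variance target in (0, 1].
#' @return list with `nComponents`, `explained` (fraction per component),
#'   `scores`, `loadings` and `center`.
#' @seealso [ghDistances()]
#' @export
pcaDescribe <- function(X, varianceTarget = 0.996) {
    X <- as.matrix(X)
    if (nrow(X) < 2) .stopf("PCA needs at least 2 rows")
    if (varianceTarget <= 0 || varianceTarget > 1)
        .stopf("varianceTarget must be in (0, 1]")
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr))
    ev <- sv$d^2
    explained <- ev / sum(ev)
    k <- which(cumsum(explained) >= varianceTarget - 1e-12)[1]
    if (is.na(k)) k <- length(explained)
    list(nComponents = k, explained = explained,
         scores = sv$u %*% diag(sv$d, length(sv$d)),
         loadings = sv$v, center = ctr)
}

#' Serialize an MPLS model to JSON
#'
#' All vectors are written at full IEEE precision, so
#' `readMPLSModel(writeMPLSModel(m, f))` round-trips losslessly.
#'
#' @param model an [MPLSModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMPLSModel <- function(model, path) {
    stopifnot(is(model, "MPLSModel"))
    doc <- list(
        class = "MPLSModel",
        constituent = model@constituent,
        treatment = list(scatter = model@treatment@scatter,
                         code = model@treatment@code),
        xCenter = model@xCenter, yCenter = model@yCenter,
        weights = model@weights, loadings = model@loadings,
        yLoadings = model@yLoadings, scalings = model@scalings,
        nFactorsMax = model@nFactorsMax,
        nFactorsSelected = model@nFactorsSelected,
        standardized = model@standardized,
        earlyStopped = model@earlyStopped,
        fittedValues = model@fittedValues, y = model@y,
        sampleIds = model@sampleIds,
        mscReference = model@mscReference,
        wavelengths = model@wavelengths)
    # I(17) significant digits: exact binary64 round trip
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         matrix = "rowmajor")
    invisible(path)
}

#' Read an MPLS model from JSON
#'
#' @param path file written by [writeMPLSModel()].
#' @return an [MPLSModel-class].
#' @export
readMPLSModel <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(doc$class, "MPLSModel"))
        .stopf("%s does not contain an MPLS model", path)
    asMat <- function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "double"
        dimnames(m) <- NULL
        m
    }
    new("MPLSModel",
        xCenter = as.numeric(doc$xCenter), yCenter = as.numeric(doc$yCenter),
        weights = asMat(doc$weights), loadings = asMat(doc$loadings),
        yLoadings = as.numeric(doc$yLoadings),
        scalings = asMat(doc$scalings),
        nFactorsMax = as.integer(doc$nFactorsMax),
        nFactorsSelected = as.integer(doc$nFactorsSelected),
        standardized = as.logical(doc$standardized),
        earlyStopped = as.logical(doc$earlyStopped),
        fittedValues = asMat(doc$fittedValues),
        y = as.numeric(doc$y), sampleIds = as.character(doc$sampleIds),
        constituent = as.character(doc$constituent),
        treatment = mathTreatment(doc$treatment$scatter,
                                  doc$treatment$code),
        mscReference = as.numeric(doc$mscReference),
        wavelengths = as.numeric(doc$wavelengths))
}
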