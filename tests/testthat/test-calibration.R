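test_that("GH distances follow the global-H convention", {
    set.seed(20)
    S <- matrix(rnorm(60 * 4), 60, 4)
    gh <- ghDistances(S, 3)
    # mean GH over the set used for the covariance is (n-1)/n
    expect_equal(mean(gh), (60 - 1) / 60, tolerance = 1e-10)
    # matches a first-principles Mahalanobis computation
    expect_equal(gh, mahalanobisOracle(S[, 1:3]) / 3, tolerance = 1e-10)
    # a sample at the centroid scores ~0
    S2 <- rbind(S, colMeans(S))
    gh2 <- ghDistances(sweep(S2, 2, colMeans(S2)), 3)
    expect_lt(gh2[61], 0.05)
    # singular covariance is reported as such
    expect_error(ghDistances(cbind(S[, 1], S[, 1]), 2), "fewer components")
})

test_that("an injected 10x-amplitude spectrum is a GH outlier", {
    st <- defaultStudySet(seed = 1L)
    X <- spectraValues(st$spectra)
    X[13, ] <- 10 * X[13, ]
    p <- pcaDescribe(X)
    gh <- ghDistances(p$scores, p$nComponents)
    expect_gt(gh[13], 3)
    expect_true(all(gh[-13] < 3))
    y <- alignReference(st$spectra, st$refs, "dry_matter")
    out <- removeOutliers(X, y, seed = 5)
    expect_true(rownames(X)[13] %in%
                out$report$sample_id[out$report$criterion == "GH"])
})

test_that("a perturbed reference value is removed by the T criterion", {
    st <- defaultStudySet(seed = 2L)
    X <- spectraValues(snv(st$spectra))
    y <- alignReference(st$spectra, st$refs, "dry_matter")
    clean <- crossValidate(X, y, seed = 5)
    secv <- clean$secv[clean$nFactors]
    y2 <- y
    y2[40] <- y2[40] + 5 * secv * 2   # gross reference error
    out <- removeOutliers(X, y2, seed = 5)
    trows <- out$report[out$report$criterion == "T", ]
    expect_true(names(y)[40] %in% trows$sample_id)
    # the reported T value is |residual| / SECV recomputed by hand on the
    # set as it stood when the criterion was applied
    ghIds <- out$report$sample_id[out$report$criterion == "GH" &
                                  out$report$pass == 1]
    keep <- setdiff(rownames(X), ghIds)
    cv <- crossValidate(X[keep, ], y2[keep], seed = 5)
    tHand <- abs(y2[keep] - cv$cvPredictions[, cv$nFactors]) /
        cv$secv[cv$nFactors]
    i40 <- match(names(y)[40], keep)
    expect_equal(unname(trows$value[trows$sample_id == names(y)[40] &
                                    trows$pass == 1]),
                 unname(tHand[i40]), tolerance = 1e-10)
})

test_that("outlier passes stop rather than trim below a fittable size", {
    set.seed(30)
    X <- matrix(rnorm(14 * 10), 14, 10)
    y <- rnorm(14)
    out <- removeOutliers(X, y, outlierConfig(hThreshold = 0.2),
                          cvGroups = 6, seed = 1)
    expect_true(out$aborted)
    expect_gte(length(out$y), 6)
})

test_that("cross-validation holds out every sample exactly once", {
    set.seed(31)
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- drop(X %*% rnorm(20)) + rnorm(40)
    cv <- crossValidate(X, y, nGroups = 6, seed = 17)
    expect_length(cv$folds, 40)
    expect_equal(sort(unique(cv$folds)), 1:6)
    expect_true(all(table(cv$folds) %in% c(6, 7)))
    expect_false(anyNA(cv$cvPredictions))
    # n = nGroups degenerates to leave-one-out
    loo <- crossValidate(X[1:6, ], y[1:6], nGroups = 6, seed = 1)
    expect_equal(sort(loo$folds), 1:6)
})

test_that("SECV equals an independent fold-by-fold refit", {
    set.seed(32)
    X <- matrix(rnorm(36 * 25), 36, 25)
    y <- drop(X %*% rnorm(25, sd = 0.3)) + rnorm(36, sd = 0.5)
    cv <- crossValidate(X, y, nGroups = 6, nFactorsMax = 5, seed = 23)
    k <- cv$nFactors
    # oracle: re-run all folds independently with the recorded partition
    press <- 0
    for (g in 1:6) {
        hold <- which(cv$folds == g)
        fit <- mplsFit(X[-hold, , drop = FALSE], y[-hold], nFactorsMax = 5)
        press <- press + sum((y[hold] -
                              predict(fit, X[hold, , drop = FALSE],
                                      nFactors = k))^2)
    }
    expect_equal(cv$secv[k], sqrt(press / 36), tolerance = 1e-10)
    # the selected count minimizes SECV
    expect_equal(min(cv$secv), cv$secv[k], tolerance = 1e-12)
})

test_that("calibration statistics match their definitions", {
    # perfect fit
    y <- c(1, 2, 3, 4, 5)
    st <- calibrationStats(y, y, y, 1)
    expect_equal(unname(st["sec"]), 0)
    expect_equal(unname(st["rsq"]), 1)
    expect_equal(unname(st["rpd"]), Inf)
    # hand-computed SEC with residuals (1, -1, 0), n = 3, k = 1
    y3 <- c(10, 20, 30)
    st3 <- calibrationStats(y3, y3 - c(1, -1, 0), y3, 1)
    expect_equal(unname(st3["sec"]), sqrt(2))
    # SD = SECV gives RPD = 1 exactly
    y4 <- c(1, 2, 3)
    st4 <- calibrationStats(y4, y4, y4 - c(1, 1, 1), 1)
    expect_equal(unname(st4["rpd"]), 1)
    expect_equal(unname(st4["secv"]), 1)
    # applicability range is mean +/- 3 SD
    expect_equal(unname(st4["rangeLow"]), 2 - 3)
    expect_equal(unname(st4["rangeHigh"]), 2 + 3)
    expect_error(calibrationStats(rep(1, 5), rep(1, 5), rep(1, 5), 1),
                 "zero variance")
})

test_that("grid search ranks by SECV with RSQ tie-break", {
    st <- defaultStudySet(seed = 3L)
    treatments <- list(mathTreatment("none"), mathTreatment("snv"),
                       mathTreatment("detrend"),
                       mathTreatment("snv", c(1, 4, 4, 1)))
    g <- gridSearch(st$spectra, st$refs, "dry_matter",
                    treatments = treatments, seed = 11)
    expect_s4_class(g, "CalibrationGrid")
    expect_length(g@results, 4)
    secv <- vapply(g@results, function(r) r@statistics[["secv"]], numeric(1))
    rsq <- vapply(g@results, function(r) r@statistics[["rsq"]], numeric(1))
    # ranking equals an independent sort of the (SECV, -RSQ) tuples
    expect_equal(order(secv, -rsq), seq_along(secv))
    # permuting the candidate list does not change the winner
    g2 <- gridSearch(st$spectra, st$refs, "dry_matter",
                     treatments = rev(treatments), seed = 11)
    expect_equal(formatTreatment(bestCalibration(g2)@treatment),
                 formatTreatment(bestCalibration(g)@treatment))
    expect_equal(sort(g2@table$secv), sort(g@table$secv), tolerance = 1e-12)
    # single-treatment grid returns it as rank 1
    g1 <- gridSearch(st$spectra, st$refs, "dry_matter",
                     treatments = treatments[2], seed = 11)
    expect_length(g1@results, 1)
    # RPD is internally consistent with SD / SECV
    s <- bestCalibration(g)@statistics
    expect_equal(unname(s["rpd"]), unname(s["sd"] / s["secv"]),
                 tolerance = 1e-10)
})

test_that("cross-validated error exceeds training error on noisy data", {
    deltas <- vapply(1:50, function(seed) {
        set.seed(seed)
        X <- matrix(rnorm(30 * 15), 30, 15)
        y <- drop(X %*% rnorm(15, sd = 0.3)) + rnorm(30, sd = 0.5)
        cv <- crossValidate(X, y, nGroups = 6, nFactorsMax = 4, seed = seed)
        fit <- mplsFit(X, y, nFactorsMax = 4)
        k <- cv$nFactors
        secTrain <- sqrt(sum((y - fit@fittedValues[, k])^2) / 30)
        cv$secv[k] - secTrain
    }, numeric(1))
    expect_gt(median(deltas), 0)
})

test_that("calibration models predict new spectra through the stored treatment", {
    st <- defaultStudySet(seed = 4L)
    ids <- unique(sampleIds(st$spectra))
    sp <- splitCalibrationValidation(ids, 70, 19, seed = 9)
    cal <- st$spectra[, sampleIds(st$spectra) %in% sp$calibration]
    val <- st$spectra[, sampleIds(st$spectra) %in% sp$validation]
    g <- gridSearch(cal, st$refs, "dry_matter",
                    treatments = list(mathTreatment("msc", c(0, 0, 1, 1))),
                    seed = 11)
    best <- bestCalibration(g)
    pred <- predict(best, val)
    expect_length(pred, 19)
    expect_equal(names(pred), sampleIds(val))
    # the MSC reference comes from the calibration set, not the new set
    refCal <- best@model@mscReference
    treatedVal <- applyTreatment(val, best@treatment, mscReference = refCal)
    expect_equal(unname(pred),
                 unname(predict(best@model, spectraValues(treatedVal))),
                 tolerance = 1e-12)
    yv <- alignReference(val, st$refs, "dry_matter")
    expect_gt(cor(pred, yv)^2, 0.3)  # real predictive signal
})
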