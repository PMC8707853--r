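test_that("SNV centres and scales each spectrum with the n-1 convention", {
    expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
    x <- randomSpectrumMatrix(1, 134, seed = 5)[1, ]
    z <- snv(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    # affine invariance and idempotence
    expect_equal(snv(3.7 * x + 0.9), z, tolerance = 1e-10)
    expect_equal(snv(z), z, tolerance = 1e-10)
    expect_error(snv(rep(2, 10)), "zero SD")
})

test_that("MSC recovers (x - a)/b against the calibration reference", {
    X <- randomSpectrumMatrix(8, 40, seed = 11)
    ref <- colMeans(X)
    out <- msc(X)
    expect_equal(attr(out, "reference"), ref)
    # the reference spectrum itself is a fixed point
    expect_equal(drop(msc(rbind(ref, X), reference = ref)[1, ]), ref,
                 tolerance = 1e-12)
    # constructed affine distortion is exactly undone
    distorted <- rbind(2 * ref + 0.5, X)
    expect_equal(unname(msc(distorted, reference = ref)[1, ]), unname(ref),
                 tolerance = 1e-12)
    # per-spectrum (a, b) match an independent normal-equations solve
    for (i in seq_len(nrow(X))) {
        ab <- solve(crossprod(cbind(1, ref)), crossprod(cbind(1, ref), X[i, ]))
        expect_equal(unname(out[i, ]), unname((X[i, ] - ab[1]) / ab[2]),
                     tolerance = 1e-10)
    }
    expect_error(msc(matrix(1:4, 1)), "at least 2 spectra")
})

test_that("detrend annihilates quadratics and matches a polyfit oracle", {
    wl <- seq(900, 1698, by = 6)
    quad <- 2 + 0.01 * wl - 1e-5 * wl^2
    expect_lt(max(abs(detrendSpectra(quad, wl))), 1e-10)
    x <- randomSpectrumMatrix(1, length(wl), seed = 3)[1, ]
    resid <- detrendSpectra(x, wl)
    # orthogonal to {1, lambda, lambda^2}
    V <- cbind(1, wl, wl^2)
    Vs <- sweep(V, 2, c(1, max(abs(wl)), max(wl^2)), "/")  # conditioning
    expect_lt(max(abs(crossprod(Vs, resid))) / length(wl), 1e-8)
    # equals the residual of an independent Vandermonde least squares
    fit <- lm(x ~ wl + I(wl^2))
    expect_equal(unname(resid), unname(residuals(fit)), tolerance = 1e-8)
    expect_error(detrendSpectra(c(1, 2), c(900, 906), order = 2),
                 "more than")
})

test_that("math code 0,0,1,1 is the identity", {
    wl <- seq(900, 1698, by = 6)
    X <- randomSpectrumMatrix(3, length(wl), seed = 9)
    out <- applyMathCode(X, c(0, 0, 1, 1), wavelengths = wl)
    expect_equal(unname(out$values), unname(X))
    expect_equal(out$wavelengths, wl)
})

test_that("first gap derivative of a channel-linear spectrum is constant m*g", {
    wl <- seq(900, by = 6, length.out = 50)
    m <- 0.37
    x <- m * seq_along(wl) + 2
    for (g in c(1, 4, 7)) {
        out <- applyMathCode(matrix(x, 1), c(1, g, 1, 1), wavelengths = wl)
        expect_equal(unname(out$values[1, ]), rep(m * g, 50 - g),
                     tolerance = 1e-12)
    }
})

test_that("math codes match the literal step-by-step oracle", {
    wl <- seq(900, 1698, by = 6)
    x <- randomSpectrumMatrix(1, 134, seed = 21)[1, ]
    cases <- list(c(2, 4, 4, 1), c(1, 4, 4, 1), c(2, 8, 6, 1),
                  c(2, 10, 10, 1), c(0, 0, 5, 3))
    for (code in cases) {
        out <- applyMathCode(matrix(x, 1), code, wavelengths = wl)
        oracle <- mathCodeOracle(x, wl, code[1], code[2], code[3], code[4])
        expect_length(out$wavelengths,
                      134 - code[1] * code[2] - (code[3] - 1) - (code[4] - 1))
        expect_equal(unname(out$values[1, ]), oracle$v, tolerance = 1e-12)
        expect_equal(out$wavelengths, oracle$w, tolerance = 1e-12)
    }
    # headline case: 134 channels - 2*4 - 3 - 0 = 123
    out <- applyMathCode(matrix(x, 1), c(2, 4, 4, 1), wavelengths = wl)
    expect_length(out$wavelengths, 123)
})

test_that("invalid math codes are rejected", {
    expect_error(mathTreatment("none", c(1, 0, 1, 1)), "gap")
    expect_error(mathTreatment("none", c(0, 0, 0, 1)), "smoothing")
    wl <- seq(900, by = 6, length.out = 10)
    expect_error(applyMathCode(matrix(1:10, 1), c(2, 4, 4, 1),
                               wavelengths = wl), "channels")
})

test_that("smoothing preserves a constant spectrum exactly", {
    x <- rep(1.234, 30)
    wl <- seq(900, by = 6, length.out = 30)
    out <- applyMathCode(matrix(x, 1), c(0, 0, 7, 5), wavelengths = wl)
    expect_equal(unname(out$values[1, ]), rep(1.234, 30 - 6 - 4))
})

test_that("all tabulated treatment strings parse to valid treatments", {
    strings <- c("Detrend only 0,0,1,1", "Standard MSC 2,10,10,1",
                 "None 2,4,4,1", "SNV only 2,4,4,1", "Detrend only 2,8,6,1",
                 "Standard MSC 0,0,1,1", "SNV only 0,0,1,1",
                 "SNV-DT 1,4,4,1", "snv-detrend 2,4,4,1", "none 0,0,1,1")
    scatters <- c("detrend", "msc", "none", "snv", "detrend", "msc", "snv",
                  "snvdt", "snvdt", "none")
    for (i in seq_along(strings)) {
        t <- parseTreatment(strings[i])
        expect_s4_class(t, "MathTreatment")
        expect_equal(t@scatter, scatters[i])
    }
    expect_equal(parseTreatment("Standard MSC 2,10,10,1")@code,
                 c(2L, 10L, 10L, 1L))
    # display form round-trips
    t <- parseTreatment("SNV only 2,4,4,1")
    expect_equal(parseTreatment(formatTreatment(t)), t)
    expect_error(parseTreatment("Fourier 1,4,4,1"), "unknown scatter")
    expect_error(parseTreatment("SNV only"), "cannot parse")
})

test_that("applyTreatment composes scatter correction then math code", {
    cfg <- tinyConfig(n = 8L, nReplicates = 1L)
    s <- generateSpectra(cfg, generateReference(cfg))
    # identity treatment
    out <- applyTreatment(s, mathTreatment("none", c(0, 0, 1, 1)))
    expect_equal(spectraValues(out), spectraValues(s))
    # SNV-DT equals detrend(snv(x))
    a <- spectraValues(applyTreatment(s, mathTreatment("snvdt", c(0, 0, 1, 1))))
    b <- detrendSpectra(snv(spectraValues(s)), wavelengths(s))
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
    # scatter first, then the code
    tr <- mathTreatment("snv", c(1, 4, 4, 1))
    c1 <- spectraValues(applyTreatment(s, tr))
    c2 <- applyMathCode(snv(spectraValues(s)), c(1, 4, 4, 1),
                        wavelengths = wavelengths(s))$values
    expect_equal(unname(c1), unname(c2), tolerance = 1e-12)
    # string form accepted
    c3 <- spectraValues(applyTreatment(s, "SNV only 1,4,4,1"))
    expect_equal(c3, c1)
})

test_that("the default grid crosses 5 scatter modes with 5 codes", {
    grid <- defaultTreatmentGrid()
    expect_length(grid, 25)
    labels <- vapply(grid, formatTreatment, character(1))
    expect_false(anyDuplicated(labels) > 0)
    # every tabulated best-model treatment is in the grid
    for (s in c("Detrend only 0,0,1,1", "Standard MSC 2,10,10,1",
                "None 2,4,4,1", "SNV only 2,4,4,1", "Detrend only 2,8,6,1",
                "Standard MSC 0,0,1,1", "SNV only 0,0,1,1"))
        expect_true(any(vapply(grid, function(g)
            identical(g, parseTreatment(s)), logical(1))))
})

test_that("MSC on a SpectraSet stores its reference for later reuse", {
    cfg <- tinyConfig(n = 6L, nReplicates = 1L)
    s <- generateSpectra(cfg, generateReference(cfg))
    out <- applyTreatment(s, mathTreatment("msc", c(0, 0, 1, 1)))
    ref <- S4Vectors::metadata(out)$mscReference
    expect_equal(unname(ref), unname(colMeans(spectraValues(s))))
    # supplying the stored reference reproduces the correction on new data
    out2 <- applyTreatment(s, mathTreatment("msc", c(0, 0, 1, 1)),
                           mscReference = ref)
    expect_equal(spectraValues(out2), spectraValues(out))
})
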