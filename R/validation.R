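# External validation statistics, descriptive statistics and the
# cultivar comparison.

#' External validation of NIR predictions
#'
#' For residuals `e = yRef - yPred`:
#' \itemize{
#'   \item `bias = mean(e)`
#'   \item mean residual `= mean(|e|)` (the signed mean is also kept)
#'   \item `RMSE = SEP = sqrt(sum(e^2) / n)` (uncorrected, denominator n)
#'   \item `SEP(C) = sqrt(sum((e - bias)^2) / (n - 1))`, the standard
#'     error of prediction corrected for bias
#'   \item paired Student t: `t = bias / (SEP(C) / sqrt(n))`, df `n - 1`,
#'     two-sided
#' }
#' Under these definitions `SEP^2 = bias^2 + SEP(C)^2 (n-1)/n` holds
#' identically. The verdict is "no difference" between reference and NIR
#' values when `p > 0.05`.
#'
#' @param yRef reference values of the validation samples.
#' @param yPred NIR-predicted values.
#' @return a [ValidationResult-class].
#' @examples
#' externalValidate(c(3, 1, 4, 2), c(1, 1, 2, 2))  # residuals 2,0,2,0
#' @export
externalValidate <- function(yRef, yPred) {
    n <- length(yRef)
    if (length(yPred) != n) .stopf("yRef and yPred must have equal length")
    if (n < 3) .stopf("external validation needs at least 3 samples")
    e <- yRef - yPred
    bias <- mean(e)
    rmse <- sqrt(sum(e^2) / n)
    sepC <- sqrt(sum((e - bias)^2) / (n - 1))
    if (sepC < 1e-300) {
        if (abs(bias) < 1e-300) { t <- 0; p <- 1 }
        else { t <- Inf * sign(bias); p <- 0 }
    } else {
        t <- bias / (sepC / sqrt(n))
        p <- 2 * pt(-abs(t), df = n - 1)
    }
    new("ValidationResult", n = as.integer(n), bias = bias,
        meanResidual = mean(abs(e)), meanSignedResidual = bias,
        rmse = rmse, sep = rmse, sepC = sepC, tStatistic = t,
        df = n - 1, pValue = p, noDifference = p > 0.05)
}

setMethod("show", "ValidationResult", function(object) {
    cat(sprintf("ValidationResult (n = %d)\n", object@n))
    cat(sprintf("  mean residual = %.4g  RMSE = SEP = %.4g  SEP(C) = %.4g  bias = %.4g\n",
                object@meanResidual, object@rmse, object@sepC, object@bias))
    cat(sprintf("  paired t = %.4g (df %g), p = %.4g -> %s\n",
                object@tStatistic, object@df, object@pValue,
                if (object@noDifference)
                    "no difference between reference and NIR values"
                else "reference and NIR values differ"))
    invisible(NULL)
})

#' Validation statistics as a one-row data.frame
#'
#' @param v a [ValidationResult-class].
#' @param constituent optional constituent label.
#' @return one-row data.frame shaped like an external validation table:
#'   mean residual, RMSE, SEP, SEP(C), bias, t, p.
#' @export
validationTable <- function(v, constituent = NA_character_) {
    data.frame(constituent = constituent, n = v@n,
               mean_residual = v@meanResidual,
               mean_signed_residual = v@meanSignedResidual,
               rmse = v@rmse, sep = v@sep, sep_c = v@sepC, bias = v@bias,
               t = v@tStatistic, p_value = v@pValue,
               no_difference = v@noDifference, stringsAsFactors = FALSE)
}

#' Descriptive statistics per group
#'
#' Arithmetic mean, sample SD (n - 1) and extremes for each group plus the
#' overall set, shaped like a sample-overview table.
#'
#' @param values numeric vector.
#' @param groups group labels (e.g. cultivars); `NULL` for overall only.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
describeGroups <- function(values, groups = NULL) {
    one <- function(label, v) {
        if (!length(v)) .stopf("group '%s' is empty", label)
        data.frame(group = label, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0,
                   min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
    out <- NULL
    if (!is.null(groups)) {
        if (length(groups) != length(values))
            .stopf("values and groups must have equal length")
        sp <- split(values, groups)
        out <- do.call(rbind, Map(one, names(sp), sp))
    }
    res <- rbind(out, one("Overall", values))
    rownames(res) <- NULL
    res
}

#' Compare a quantity across groups (Kruskal--Wallis)
#'
#' Rank-based comparison with tie correction, the test used for the
#' cultivar comparison of the reference values. When every value is
#' identical the test is undefined and `H = 0, p = 1` is returned by
#' convention.
#'
#' @param values numeric vector.
#' @param groups group labels, at least two non-empty groups.
#' @return list with `statistic` (H), `parameter` (df) and `p.value`.
#' @export
compareGroups <- function(values, groups) {
    if (length(values) != length(groups))
        .stopf("values and groups must have equal length")
    groups <- factor(groups)
    if (nlevels(droplevels(groups)) < 2)
        .stopf("need at least two non-empty groups")
    if (length(unique(values)) == 1)
        return(list(statistic = 0, parameter = nlevels(groups) - 1,
                    p.value = 1))
    kt <- kruskal.test(values, groups)
    list(statistic = unname(kt$statistic), parameter = unname(kt$parameter),
         p.value = kt$p.value)
}
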