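#' @name nircal-generics
#' @title Generics defined by nircal
#' @description S4 generics for spectra accessors and preprocessing
#'   operators. See the methods for details: [spectraValues()],
#'   [wavelengths()], [snv()], [msc()], [detrendSpectra()],
#'   [applyMathCode()], [applyTreatment()].
#' @param x object
#' @param ... passed to methods
#' @return see individual methods
NULL

#' @rdname nircal-generics
#' @export
setGeneric("spectraValues", function(x) standardGeneric("spectraValues"))

#' @rdname nircal-generics
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname nircal-generics
#' @export
setGeneric("spectraMode", function(x) standardGeneric("spectraMode"))

#' @rdname nircal-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname nircal-generics
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @rdname nircal-generics
#' @export
setGeneric("cultivarLabels", function(x) standardGeneric("cultivarLabels"))

#' @rdname nircal-generics
#' @export
setGeneric("toAbsorbance", function(x) standardGeneric("toAbsorbance"))

#' @rdname nircal-generics
#' @export
setGeneric("averageReplicates",
           function(x) standardGeneric("averageReplicates"))

#' @rdname nircal-generics
#' @export
setGeneric("snv", function(x, ...) standardGeneric("snv"))

#' @rdname nircal-generics
#' @export
setGeneric("msc", function(x, ...) standardGeneric("msc"))

#' @rdname nircal-generics
#' @export
setGeneric("detrendSpectra", function(x, ...)
    standardGeneric("detrendSpectra"))

#' @rdname nircal-generics
#' @export
setGeneric("applyMathCode", function(x, code, ...)
    standardGeneric("applyMathCode"))

#' @rdname nircal-generics
#' @export
setGeneric("applyTreatment", function(x, treatment, ...)
    standardGeneric("applyTreatment"))
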