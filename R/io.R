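# CSV interchange. Spectra are written wide -- sample_id, replicate,
# cultivar, then one wl_<nm> column per channel -- with a leading
# "# mode=..." comment so reflectance/absorbance survives the round trip.
# Floats are written with %.17g so write/read is bit-lossless.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write spectra to a wide CSV file
#'
#' @param x a [SpectraSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(x, path) {
    stopifnot(is(x, "SpectraSet"))
    v <- spectraValues(x)
    wl <- wavelengths(x)
    header <- c("sample_id", "replicate", "cultivar",
                paste0("wl_", format(wl, trim = TRUE, scientific = FALSE)))
    rep <- replicateIds(x)
    cult <- cultivarLabels(x)
    rows <- vapply(seq_len(nrow(v)), function(i) {
        paste(c(sampleIds(x)[i],
                if (is.na(rep[i])) "" else as.character(rep[i]),
                if (is.na(cult[i])) "" else cult[i],
                .fmtNum(v[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(sprintf("# mode=%s", spectraMode(x)),
                 paste(header, collapse = ","), rows), path)
    invisible(path)
}

# split one CSV line, complaining with its line number on mismatch
.splitLine <- function(line, nExpected, lineNo) {
    cells <- strsplit(line, ",", fixed = TRUE)[[1]]
    # trailing empty cell is dropped by strsplit; restore it
    if (length(cells) == nExpected - 1 && grepl(",$", line))
        cells <- c(cells, "")
    if (length(cells) != nExpected)
        .stopf("parse error at line %d: %d cells, expected %d",
               lineNo, length(cells), nExpected)
    cells
}

.asNum <- function(cells, lineNo, what) {
    suppressWarnings(v <- as.numeric(cells))
    if (anyNA(v))
        .stopf("parse error at line %d: non-numeric %s '%s'",
               lineNo, what, cells[which(is.na(v))[1]])
    v
}

#' Read spectra from a wide CSV file
#'
#' Expects the layout written by [writeSpectra()]: an optional
#' `# mode=` comment, a header declaring `wl_<nm>` wavelength columns in
#' strictly increasing order, and one spectrum per row. Ragged rows,
#' non-numeric cells and unsorted wavelength headers raise a parse error
#' with the offending line number.
#'
#' @param path input file.
#' @param mode measurement mode used when the file carries no `# mode=`
#'   comment.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path, mode = c("absorbance", "reflectance")) {
    mode <- match.arg(mode)
    lines <- readLines(path)
    if (!length(lines)) .stopf("empty file: %s", path)
    offset <- 0L
    if (grepl("^#", lines[1])) {
        m <- regmatches(lines[1], regexec("mode=(\\w+)", lines[1]))[[1]]
        if (length(m) == 2) mode <- m[2]
        lines <- lines[-1]
        offset <- 1L
    }
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    wlCols <- grep("^wl_", header)
    if (!length(wlCols))
        .stopf("parse error at line %d: no wl_ wavelength columns in header",
               offset + 1L)
    wl <- .asNum(sub("^wl_", "", header[wlCols]), offset + 1L, "wavelength")
    if (any(diff(wl) <= 0))
        .stopf("parse error at line %d: wavelength columns out of order",
               offset + 1L)
    body <- lines[-1]
    if (!length(body)) .stopf("no spectra rows in %s", path)
    n <- length(body)
    values <- matrix(NA_real_, n, length(wlCols))
    ids <- character(n); reps <- character(n); cult <- character(n)
    idCol <- match("sample_id", header)
    repCol <- match("replicate", header)
    cultCol <- match("cultivar", header)
    if (is.na(idCol)) .stopf("header is missing the sample_id column")
    for (i in seq_len(n)) {
        lineNo <- offset + 1L + i
        cells <- .splitLine(body[i], length(header), lineNo)
        ids[i] <- cells[idCol]
        reps[i] <- if (is.na(repCol)) "" else cells[repCol]
        cult[i] <- if (is.na(cultCol)) "" else cells[cultCol]
        values[i, ] <- .asNum(cells[wlCols], lineNo, "cell")
    }
    repIds <- suppressWarnings(as.integer(reps))
    SpectraSet(values, wl, ids,
               replicateIds = if (all(is.na(repIds))) NULL else repIds,
               cultivar = if (all(cult == "" | is.na(cult))) NULL else
                   ifelse(cult == "", NA_character_, cult),
               mode = mode)
}

#' Write a reference table to CSV
#'
#' @param refs data.frame with columns `sample_id`, `cultivar` (optional)
#'   and one column per constituent.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReference <- function(refs, path) {
    num <- vapply(refs, is.numeric, logical(1))
    out <- refs
    out[num] <- lapply(refs[num], .fmtNum)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a reference table from CSV
#'
#' Checks the invariants of a reference table: unique sample ids and
#' finite, non-negative constituent values.
#'
#' @param path input file with a `sample_id` column and numeric
#'   constituent columns (e.g. `dry_matter`, `reducing_sugars`).
#' @return data.frame.
#' @export
readReference <- function(path) {
    refs <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(refs))
        .stopf("reference file is missing the sample_id column")
    refs$sample_id <- as.character(refs$sample_id)
    if (anyDuplicated(refs$sample_id))
        .stopf("duplicate sample ids in reference table: %s",
               paste(unique(refs$sample_id[duplicated(refs$sample_id)]),
                     collapse = ", "))
    num <- setdiff(names(refs)[vapply(refs, is.numeric, logical(1))], NULL)
    for (cn in num) {
        if (any(!is.finite(refs[[cn]])))
            .stopf("non-finite values in reference column '%s'", cn)
        if (any(refs[[cn]] < 0))
            .stopf("negative values in reference column '%s'", cn)
    }
    refs
}

#' Align reference values with a spectra set
#'
#' Joins the reference table against the sample ids of a spectra set and
#' returns the constituent vector in spectra order. Samples present in the
#' spectra but absent from the reference table raise an error listing the
#' missing ids.
#'
#' @param x a [SpectraSet-class] (typically replicate-averaged).
#' @param refs reference data.frame with a `sample_id` column.
#' @param constituent name of the reference column to extract.
#' @return named numeric vector aligned with `sampleIds(x)`.
#' @export
alignReference <- function(x, refs, constituent) {
    if (!constituent %in% names(refs))
        .stopf("constituent '%s' not found in reference table", constituent)
    ids <- unique(sampleIds(x))
    missing <- setdiff(ids, refs$sample_id)
    if (length(missing))
        .stopf("reference table is missing %d sample(s): %s",
               length(missing), paste(missing, collapse = ", "))
    y <- refs[[constituent]][match(ids, refs$sample_id)]
    names(y) <- ids
    y
}
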