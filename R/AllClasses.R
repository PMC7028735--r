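#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData assays
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

#' Container for per-probe SNP-array Log R Ratios
#'
#' `ArrayLRRSet` extends `RangedSummarizedExperiment` with a single assay
#' named `"LRR"` holding per-probe log2 intensity ratios (probes in rows,
#' samples in columns).  Row ranges carry probe coordinates (1-based) and a
#' `probeId` metadata column; column data carries at least `sampleId`,
#' `subjectId` and `batchId`, plus any further sample metadata such as
#' `age` or `arrayVersion`.  Missing LRR values are `NA`, never 0.
#'
#' @slot .  Inherits all slots from
#'   [SummarizedExperiment::RangedSummarizedExperiment-class].
#'
#' @seealso [readLRRReport()], [computeMLRRY()], [qcSamples()]
#' @export
setClass("ArrayLRRSet",
    contains = "RangedSummarizedExperiment")

setValidity("ArrayLRRSet", function(object) {
    msg <- NULL
    if (!"LRR" %in% assayNames(object))
        msg <- c(msg, "assay 'LRR' is required")
    if (nrow(object) == 0L)
        msg <- c(msg, "at least one probe is required")
    if (is.null(rowRanges(object)$probeId))
        msg <- c(msg, "rowRanges must carry a 'probeId' column")
    else if (anyDuplicated(rowRanges(object)$probeId))
        msg <- c(msg, "probe ids must be unique")
    cd <- colData(object)
    for (col in c("sampleId", "subjectId", "batchId"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData must carry '%s'", col))
    if ("sampleId" %in% colnames(cd) && anyDuplicated(cd$sampleId))
        msg <- c(msg, "sample ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct an ArrayLRRSet
#'
#' @param lrr Numeric matrix of Log R Ratios, probes in rows and samples in
#'   columns.  `NA` marks missing measurements.
#' @param probes A [GenomicRanges::GRanges] of probe positions (width-1
#'   ranges, 1-based) with a `probeId` metadata column, parallel to the rows
#'   of `lrr`.
#' @param sampleInfo A `data.frame` or [S4Vectors::DataFrame] parallel to the
#'   columns of `lrr`, with columns `sampleId`, `subjectId`, `batchId` (and
#'   optionally `age`, `arrayVersion`, ...).  `subjectId`/`batchId` default
#'   to `sampleId` / `"batch1"` when absent.
#'
#' @return An [ArrayLRRSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("Y", IRanges::IRanges(3e6 + 1:3, width = 1),
#'     probeId = paste0("p", 1:3))
#' m <- matrix(c(-0.1, 0, -0.2), ncol = 1,
#'     dimnames = list(NULL, "s1"))
#' ArrayLRRSet(m, gr, data.frame(sampleId = "s1"))
#' @export
ArrayLRRSet <- function(lrr, probes, sampleInfo) {
    lrr <- as.matrix(lrr)
    sampleInfo <- DataFrame(sampleInfo)
    if (is.null(sampleInfo$sampleId)) {
        if (!is.null(colnames(lrr)))
            sampleInfo$sampleId <- colnames(lrr)
        else
            stop("sampleInfo must carry 'sampleId' (or lrr column names)")
    }
    if (is.null(sampleInfo$subjectId))
        sampleInfo$subjectId <- sampleInfo$sampleId
    if (is.null(sampleInfo$batchId))
        sampleInfo$batchId <- "batch1"
    colnames(lrr) <- sampleInfo$sampleId
    se <- SummarizedExperiment(assays = list(LRR = lrr),
        rowRanges = probes, colData = sampleInfo)
    new("ArrayLRRSet", se)
}

#' @describeIn ArrayLRRSet Number of probes and samples at a glance.
#' @param object An `ArrayLRRSet`.
#' @export
setMethod("show", "ArrayLRRSet", function(object) {
    cat(sprintf("ArrayLRRSet: %d probes x %d samples\n",
        nrow(object), ncol(object)))
    chr <- as.character(seqnames(rowRanges(object)))
    cat(sprintf("  chrY probes: %d | batches: %s\n",
        sum(chr == "Y"),
        paste(unique(colData(object)$batchId), collapse = ", ")))
    callNextMethod()
})

#' Power-law calibration between antiloged mLRRY and measured Y fraction
#'
#' Holds the fit `y = a * (2^mLRRY)^b` relating the antiloged array statistic
#' to the Y-chromosome cell fraction measured by an orthogonal technology
#' (sequencing depth or droplet digital PCR), together with the
#' integer-rounded constants that define the closed-form transformation
#' to percentage of cells with LOY.
#'
#' @slot a Fitted scale constant (> 0).
#' @slot b Fitted exponent.
#' @slot aRounded `a` rounded to the nearest integer (half away from zero).
#' @slot bRounded `b` rounded to the nearest integer.
#' @slot rSquared Coefficient of determination of the log-log fit.
#' @slot n Number of pairs used.
#' @slot nExcluded Pairs dropped because the measured fraction was <= 0.
#' @slot method `"loglog"` (ordinary least squares on the log scale) or
#'   `"nls"` (nonlinear least squares on the natural scale).
#'
#' @seealso [fitPowerCalibration()]
#' @export
setClass("CalibrationFit",
    representation(a = "numeric", b = "numeric",
        aRounded = "integer", bRounded = "integer",
        rSquared = "numeric", n = "integer", nExcluded = "integer",
        method = "character"))

setValidity("CalibrationFit", function(object) {
    msg <- NULL
    if (length(object@a) != 1L || object@a <= 0)
        msg <- c(msg, "'a' must be a single positive number")
    if (length(object@b) != 1L)
        msg <- c(msg, "'b' must be a single number")
    if (object@n < 3L)
        msg <- c(msg, "at least 3 pairs are required")
    if (length(object@rSquared) == 1L &&
        (object@rSquared < 0 || object@rSquared > 1 + 1e-12))
        msg <- c(msg, "'rSquared' must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CalibrationFit Compact display of the fitted power equation.
#' @param object A `CalibrationFit`.
#' @export
setMethod("show", "CalibrationFit", function(object) {
    cat(sprintf("CalibrationFit (%s): y = %.4f * (2^mLRRY)^%.4f\n",
        object@method, object@a, object@b))
    cat(sprintf("  rounded constants: a = %d, b = %d | R^2 = %.4f | n = %d",
        object@aRounded, object@bRounded, object@rSquared, object@n))
    if (object@nExcluded > 0L)
        cat(sprintf(" | excluded (y <= 0): %d", object@nExcluded))
    cat("\n")
})
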