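#' Median Log R Ratio over MSY probes (mLRRY)
#'
#' The mLRRY statistic summarises a sample's male-specific-region probe
#' intensities as their median: 0 for a typical male without loss, more
#' negative with increasing fractions of cells lacking chromosome Y, and
#' around -3 to -4 for female samples.  The median (rather than the mean)
#' keeps outlier probes, e.g. in ampliconic regions, from dominating the
#' estimate.
#'
#' For a numeric vector the median is returned directly (even counts
#' average the two central order statistics); `NA` values are removed
#' first, and fewer than `minProbes` remaining values yield `NA`.  For an
#' [ArrayLRRSet-class] the statistic is computed per sample over probes
#' selected by [selectMSYProbes()].
#'
#' @param x Numeric vector of MSY LRR values, or an [ArrayLRRSet-class].
#' @param minProbes Minimum number of non-missing MSY probes required for a
#'   robust median (default 100).
#' @param ... Passed to methods.
#' @return A single numeric for the vector method (`NA` when under-powered);
#'   a named numeric vector, one element per sample, for the
#'   `ArrayLRRSet` method.
#' @examples
#' computeMLRRY(c(-0.2, 0, -0.4), minProbes = 1)        # -0.2
#' computeMLRRY(c(-0.2, 0, -0.4, 5), minProbes = 1)     # -0.1
#' @export
setGeneric("computeMLRRY", function(x, ...) standardGeneric("computeMLRRY"))

#' @rdname computeMLRRY
#' @export
setMethod("computeMLRRY", "numeric", function(x, minProbes = 100L, ...) {
    x <- x[!is.na(x)]
    if (length(x) < minProbes)
        return(NA_real_)
    stats::median(x)
})

#' @rdname computeMLRRY
#' @param region MSY interval (see [msyRegion()]).
#' @export
setMethod("computeMLRRY", "ArrayLRRSet",
    function(x, minProbes = 100L, region = msyRegion(), ...) {
        vals <- msyLrrValues(x, region = region)
        vapply(vals, computeMLRRY, numeric(1), minProbes = minProbes)
    })

#' Per-sample quality control and raw mLRRY table
#'
#' Applies the experiment-level quality criteria before any mLRRY-based
#' estimate is trusted: enough non-missing MSY probes for a robust median,
#' bounded genome-wide LRR standard deviation (a noisy-array criterion), and
#' bounded overall missingness.  QC failure is a recorded data state, never
#' an exception, and no sample is dropped: every input sample appears in the
#' output with `qcPass` and the reasons it failed, if any.
#'
#' The noise criterion is computed over autosomal probes: on chromosome Y
#' the probe intensities carry the LOY signal itself, and a strongly mosaic
#' sample must not be mistaken for a noisy array.
#'
#' @param x An [ArrayLRRSet-class].
#' @param minProbes Minimum non-missing MSY probes (default 100).
#' @param maxLrrSd Maximum autosomal standard deviation of LRR
#'   (default 0.30).
#' @param maxMissing Maximum fraction of missing LRR values (default 0.05).
#' @param region MSY interval.
#' @return A [S4Vectors::DataFrame] with one row per sample: `sampleId`,
#'   `subjectId`, `batchId`, `nMsyProbes`, `lrrSd`, `fracMissing`,
#'   `mlrryRaw` (`NA` when under the probe minimum), `qcPass`, and
#'   `qcReasons` (comma-separated criterion names, empty when passing).
#' @export
qcSamples <- function(x, minProbes = 100L, maxLrrSd = 0.30,
                      maxMissing = 0.05, region = msyRegion()) {
    stopifnot(is(x, "ArrayLRRSet"))
    lrr <- assay(x, "LRR")
    msy <- msyLrrValues(x, region = region)
    n <- ncol(x)
    nMsy <- vapply(msy, length, integer(1))
    auto <- as.character(seqnames(rowRanges(x))) %in% as.character(1:22)
    lrrSd <- apply(lrr[auto, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    fracMissing <- colMeans(is.na(lrr))
    mlrry <- vapply(msy, computeMLRRY, numeric(1), minProbes = minProbes)
    reasons <- vapply(seq_len(n), function(j) {
        r <- character(0)
        if (nMsy[j] < minProbes) r <- c(r, "min_probes")
        if (is.finite(lrrSd[j]) && lrrSd[j] > maxLrrSd)
            r <- c(r, "max_lrr_sd")
        if (fracMissing[j] > maxMissing) r <- c(r, "max_missing")
        paste(r, collapse = ",")
    }, character(1))
    DataFrame(sampleId = colData(x)$sampleId,
        subjectId = colData(x)$subjectId,
        batchId = colData(x)$batchId,
        nMsyProbes = unname(nMsy),
        lrrSd = unname(lrrSd),
        fracMissing = unname(fracMissing),
        mlrryRaw = unname(mlrry),
        qcPass = reasons == "",
        qcReasons = reasons)
}

#' Estimate the mode of a batch's mLRRY distribution by kernel density
#'
#' The dominant mode of a batch's mLRRY values sits at the batch's
#' technical offset because samples without Y loss (mLRRY near 0) dominate
#' any realistic cohort; subtracting it re-centres the batch.  The density
#' is a Gaussian-kernel estimate (bandwidth by Silverman's rule of thumb,
#' `"nrd0"`, or any rule [stats::density] accepts) on a 512-point grid
#' spanning `[min - 3h, max + 3h]`; ties in the density maximum are broken
#' toward the grid point closest to zero, since no-loss samples are expected
#' to dominate.
#'
#' @param x Numeric vector of per-sample mLRRY values (one batch).
#' @param bw Bandwidth rule or numeric bandwidth for [stats::density].
#' @param minBatchN Minimum batch size for a trustworthy mode (default 25).
#' @return A list with `mode`, `bandwidth` and `n`, or `NULL` (with a
#'   warning) when fewer than `minBatchN` usable values are supplied.
#' @examples
#' set.seed(1)
#' estimateBatchMode(rnorm(500, -0.30, 0.05))$mode  # close to -0.30
#' @export
estimateBatchMode <- function(x, bw = "nrd0", minBatchN = 25L) {
    x <- x[is.finite(x)]
    if (length(x) < minBatchN) {
        warning(sprintf(
            "batch has %d usable values (< %d); correction unavailable",
            length(x), minBatchN))
        return(NULL)
    }
    if (stats::sd(x) == 0)
        return(list(mode = x[1], bandwidth = 0, n = length(x)))
    h <- if (is.numeric(bw)) bw else
        switch(bw, nrd0 = stats::bw.nrd0(x), nrd = stats::bw.nrd(x),
            SJ = stats::bw.SJ(x), stop("unknown bandwidth rule: ", bw))
    d <- stats::density(x, bw = h, n = 512,
        from = min(x) - 3 * h, to = max(x) + 3 * h)
    top <- which(d$y >= max(d$y) - 1e-12 * abs(max(d$y)))
    mode <- d$x[top[which.min(abs(d$x[top]))]]
    list(mode = mode, bandwidth = h, n = length(x))
}

#' Batch-correct raw mLRRY values by mode subtraction
#'
#' For each batch with at least `minBatchN` QC-passing samples, subtracts
#' the kernel-density mode of its raw mLRRY values
#' (see [estimateBatchMode()]); the raw values are retained unchanged.
#' Batches too small to correct keep the raw value with
#' `batchCorrected = FALSE`.  The correction is location-equivariant:
#' shifting a whole batch by a constant leaves its corrected values
#' unchanged up to grid resolution.
#'
#' @param mlrry A table from [qcSamples()] (needs `mlrryRaw`, `batchId`,
#'   `qcPass`).
#' @param bw,minBatchN Passed to [estimateBatchMode()].
#' @param perBatch Correct per batch label (default) or cohort-wide.
#' @return The input with columns `mlrryCorrected` and `batchCorrected`
#'   appended, plus a `batchModes` entry in `metadata()` listing the mode,
#'   bandwidth and size per batch.
#' @export
correctBatchEffects <- function(mlrry, bw = "nrd0", minBatchN = 25L,
                                perBatch = TRUE) {
    stopifnot(all(c("mlrryRaw", "batchId", "qcPass") %in% colnames(mlrry)))
    mlrry$mlrryCorrected <- mlrry$mlrryRaw
    mlrry$batchCorrected <- FALSE
    batches <- if (perBatch) unique(mlrry$batchId) else "all"
    modes <- list()
    for (b in batches) {
        sel <- if (perBatch) mlrry$batchId == b else rep(TRUE, nrow(mlrry))
        fitSel <- sel & mlrry$qcPass & is.finite(mlrry$mlrryRaw)
        est <- suppressWarnings(
            estimateBatchMode(mlrry$mlrryRaw[fitSel], bw = bw,
                minBatchN = minBatchN))
        if (is.null(est)) {
            warning(sprintf(
                "batch '%s' below minimum size; raw values kept", b))
            next
        }
        modes[[as.character(b)]] <- est
        mlrry$mlrryCorrected[sel] <- mlrry$mlrryRaw[sel] - est$mode
        mlrry$batchCorrected[sel] <- TRUE
    }
    if (is(mlrry, "DataFrame"))
        metadata(mlrry)$batchModes <- modes
    else
        attr(mlrry, "batchModes") <- modes
    mlrry
}

#' Apply one batch correction to one sample's result row
#'
#' Low-level counterpart of [correctBatchEffects()] for a single sample:
#' subtracts a previously estimated batch mode, erroring if the batch
#' labels disagree.
#'
#' @param result A single-row mLRRY table (needs `mlrryRaw`, `batchId`).
#' @param correction A list with `mode` and `batchId`.
#' @return `result` with `mlrryCorrected` filled in; raw value untouched.
#' @export
applyBatchCorrection <- function(result, correction) {
    stopifnot(nrow(result) == 1L, !is.null(correction$mode))
    if (!is.null(correction$batchId) &&
        as.character(result$batchId) != as.character(correction$batchId))
        stop(sprintf("batch mismatch: sample batch '%s' vs correction batch '%s'",
            result$batchId, correction$batchId))
    if (!is.finite(result$mlrryRaw))
        stop("mlrryRaw is missing; nothing to correct")
    result$mlrryCorrected <- result$mlrryRaw - correction$mode
    result$batchCorrected <- TRUE
    result
}
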