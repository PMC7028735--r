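#' Male-specific region of chromosome Y
#'
#' Returns the male-specific region (MSY) of chromosome Y as a width-one
#' `GRanges`, by default chrY:2,781,480-56,887,902 (1-based, closed
#' interval).  Probes inside this region, which excludes the
#' pseudo-autosomal regions shared with chromosome X, are the basis of the
#' mLRRY statistic.  The coordinates are a parameter, not a constant, so
#' build-specific ranges can be supplied.
#'
#' @param start,end 1-based inclusive boundaries of the region.
#' @return A [GenomicRanges::GRanges] of length 1 on chromosome Y.
#' @examples
#' msyRegion()
#' @export
msyRegion <- function(start = 2781480L, end = 56887902L) {
    stopifnot(start >= 1L, start <= end)
    GRanges("Y", IRanges(start = start, end = end))
}

#' Read a long-format SNP-array intensity report with its probe manifest
#'
#' Parses a tab-delimited Final-Report-like file with one row per
#' sample-by-probe measurement (columns `Sample ID`, `SNP Name`,
#' `Log R Ratio`) and joins probe coordinates from a manifest CSV
#' (columns `SNP Name`, `Chr`, `Position`, 1-based).  Probes present in the
#' report but absent from the manifest are dropped with a warning; the
#' dropped count is kept in `metadata(x)$droppedProbes`.  `NA`, `NaN` and
#' blank LRR fields all parse as missing.
#'
#' @param report Path to the tab-delimited intensity report.
#' @param manifest Path to the probe-manifest CSV.
#' @param sampleInfo Optional `data.frame` with `sampleId` (matching
#'   `Sample ID`) plus `subjectId`, `batchId`, `age`, ... to attach as
#'   column data.
#' @return An [ArrayLRRSet-class]; probes ordered by (chrom, pos), samples
#'   by sample id.  An empty report body yields a zero-column object.
#' @seealso [readLRRMatrix()] for the wide-matrix dialect,
#'   [writeLRRReport()] for the inverse.
#' @export
readLRRReport <- function(report, manifest, sampleInfo = NULL) {
    rep <- utils::read.delim(report, check.names = FALSE,
        colClasses = "character", na.strings = c("NA", "NaN", ""))
    need <- c("Sample ID", "SNP Name", "Log R Ratio")
    miss <- setdiff(need, colnames(rep))
    if (length(miss))
        stop("report is missing required column(s): ",
            paste(miss, collapse = ", "))
    man <- .readManifest(manifest)
    long <- data.frame(sampleId = rep[["Sample ID"]],
        probeId = rep[["SNP Name"]],
        lrr = suppressWarnings(as.numeric(rep[["Log R Ratio"]])),
        stringsAsFactors = FALSE)
    .assembleArraySet(long, man, sampleInfo)
}

#' Read a wide LRR matrix (probes x samples)
#'
#' Convenience reader for the wide dialect: a tab-delimited file whose first
#' column is `SNP Name` and remaining columns are one sample each.
#' Converted to the long representation internally and assembled exactly as
#' [readLRRReport()].
#'
#' @inheritParams readLRRReport
#' @param path Path to the wide tab-delimited matrix.
#' @return An [ArrayLRRSet-class].
#' @export
readLRRMatrix <- function(path, manifest, sampleInfo = NULL) {
    wide <- utils::read.delim(path, check.names = FALSE,
        na.strings = c("NA", "NaN", ""))
    if (!"SNP Name" %in% colnames(wide))
        stop("report is missing required column(s): SNP Name")
    samples <- setdiff(colnames(wide), "SNP Name")
    long <- data.frame(
        sampleId = rep(samples, each = nrow(wide)),
        probeId = rep(wide[["SNP Name"]], times = length(samples)),
        lrr = as.numeric(unlist(wide[samples], use.names = FALSE)),
        stringsAsFactors = FALSE)
    .assembleArraySet(long, .readManifest(manifest), sampleInfo)
}

.readManifest <- function(manifest) {
    man <- utils::read.csv(manifest, check.names = FALSE,
        colClasses = "character")
    need <- c("SNP Name", "Chr", "Position")
    miss <- setdiff(need, colnames(man))
    if (length(miss))
        stop("manifest is missing required column(s): ",
            paste(miss, collapse = ", "))
    data.frame(probeId = man[["SNP Name"]],
        chrom = .normalizeChrom(man[["Chr"]]),
        pos = as.integer(man[["Position"]]),
        stringsAsFactors = FALSE)
}

.assembleArraySet <- function(long, man, sampleInfo) {
    known <- long$probeId %in% man$probeId
    dropped <- sum(!known)
    if (dropped > 0L) {
        warning(sprintf("%d report row(s) reference probes absent from the manifest; dropped",
            dropped))
        long <- long[known, , drop = FALSE]
    }
    samples <- sort(unique(long$sampleId))
    man <- man[order(match(man$chrom, .CANONICAL_CHROMS), man$pos), ]
    used <- man[man$probeId %in% long$probeId, , drop = FALSE]
    lrr <- matrix(NA_real_, nrow = nrow(used), ncol = length(samples),
        dimnames = list(used$probeId, samples))
    if (nrow(long))
        lrr[cbind(match(long$probeId, used$probeId),
                  match(long$sampleId, samples))] <- long$lrr
    info <- DataFrame(sampleId = samples)
    if (!is.null(sampleInfo)) {
        sampleInfo <- DataFrame(sampleInfo)
        if (is.null(sampleInfo$sampleId))
            stop("sampleInfo must carry 'sampleId'")
        idx <- match(samples, sampleInfo$sampleId)
        if (anyNA(idx))
            stop("sampleInfo lacks metadata for sample(s): ",
                paste(samples[is.na(idx)], collapse = ", "))
        info <- sampleInfo[idx, , drop = FALSE]
    }
    if (length(samples) == 0L) {
        # empty report body: no samples, but keep the manifest as rows
        gr <- GRanges(man$chrom, IRanges(man$pos, width = 1),
            probeId = man$probeId)
        obj <- ArrayLRRSet(matrix(numeric(0), nrow = nrow(man), ncol = 0),
            gr, DataFrame(sampleId = character(0),
                subjectId = character(0), batchId = character(0)))
        metadata(obj)$droppedProbes <- dropped
        return(obj)
    }
    gr <- GRanges(used$chrom, IRanges(used$pos, width = 1),
        probeId = used$probeId)
    obj <- ArrayLRRSet(lrr, gr, info)
    metadata(obj)$droppedProbes <- dropped
    obj
}

#' Write an ArrayLRRSet back to the long report dialect
#'
#' Inverse of [readLRRReport()]: emits one row per sample-by-probe
#' measurement with columns `Sample ID`, `SNP Name`, `Log R Ratio` (missing
#' values as `NaN`, matching scanner output), and optionally the matching
#' manifest CSV.  Reading the pair back reproduces the probe records
#' exactly (LRR to the printed precision).
#'
#' @param x An [ArrayLRRSet-class].
#' @param report Output path for the tab-delimited report.
#' @param manifest Optional output path for the probe-manifest CSV.
#' @param digits Significant digits used to print LRR values.
#' @return Invisibly, the report path.
#' @export
writeLRRReport <- function(x, report, manifest = NULL, digits = 6) {
    stopifnot(is(x, "ArrayLRRSet"))
    gr <- rowRanges(x)
    lrr <- assay(x, "LRR")
    samples <- colData(x)$sampleId
    long <- data.frame(
        `Sample ID` = rep(samples, each = nrow(x)),
        `SNP Name` = rep(gr$probeId, times = ncol(x)),
        `Log R Ratio` = formatC(as.vector(lrr), digits = digits,
            format = "g"),
        check.names = FALSE, stringsAsFactors = FALSE)
    long[["Log R Ratio"]][is.na(as.vector(lrr))] <- "NaN"
    utils::write.table(long, report, sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(manifest)) {
        man <- data.frame(`SNP Name` = gr$probeId,
            Chr = as.character(seqnames(gr)),
            Position = start(gr), check.names = FALSE)
        utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
    }
    invisible(report)
}

#' Select probes inside the male-specific region of chromosome Y
#'
#' Restricts an `ArrayLRRSet` to probes on chromosome Y whose position falls
#' inside the closed interval given by `region` (both boundaries included).
#' A filter: the result's probes are a subset of the input's, in the same
#' order, and applying the selection twice equals applying it once.
#'
#' @param x An [ArrayLRRSet-class].
#' @param region The MSY interval, a `GRanges` as returned by [msyRegion()].
#' @return An [ArrayLRRSet-class] holding only MSY probes (possibly zero).
#' @examples
#' ## a probe at the lower boundary 2,781,480 is retained;
#' ## one base below is not
#' @export
selectMSYProbes <- function(x, region = msyRegion()) {
    stopifnot(is(x, "ArrayLRRSet"), is(region, "GRanges"))
    gr <- rowRanges(x)
    keep <- as.character(seqnames(gr)) == as.character(seqnames(region))[1] &
        start(gr) >= start(region)[1] & start(gr) <= end(region)[1]
    x[keep, ]
}

#' Per-sample MSY LRR values
#'
#' Extracts, for one sample, the vector of LRR values of MSY probes with
#' missing measurements removed — the direct input of [computeMLRRY()].
#'
#' @param x An [ArrayLRRSet-class].
#' @param sample Sample id (default: all samples).
#' @param region MSY interval.
#' @return A named list (one element per requested sample) of numeric
#'   vectors.
#' @export
msyLrrValues <- function(x, sample = NULL, region = msyRegion()) {
    msy <- selectMSYProbes(x, region)
    ids <- colData(msy)$sampleId
    if (!is.null(sample)) {
        if (!all(sample %in% ids))
            stop("unknown sample id(s): ",
                paste(setdiff(sample, ids), collapse = ", "))
        msy <- msy[, match(sample, ids)]
        ids <- sample
    }
    lrr <- assay(msy, "LRR")
    out <- lapply(seq_along(ids), function(j) {
        v <- unname(lrr[, j])
        v[!is.na(v)]
    })
    names(out) <- ids
    out
}
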