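#' Read a windowed read-count table
#'
#' Reads a BED-like tab-delimited table of non-overlapping genomic windows
#' with per-window read counts and annotations: columns `chrom`,
#' `start` (0-based), `end` (exclusive), `count`, `gc` (fraction in
#' \[0,1\]), `mappability` (fraction in \[0,1\]).  Chromosome names are
#' normalised (`chrY` -> `Y`).
#'
#' @param path Path to the tab-delimited window table (with header).
#' @return A `data.frame` of windows, invariants checked (start < end,
#'   counts >= 0, gc/mappability within \[0,1\]).
#' @export
readDepthWindows <- function(path) {
    w <- utils::read.delim(path, check.names = FALSE)
    need <- c("chrom", "start", "end", "count", "gc", "mappability")
    miss <- setdiff(need, colnames(w))
    if (length(miss))
        stop("window table is missing required column(s): ",
            paste(miss, collapse = ", "))
    w$chrom <- .normalizeChrom(w$chrom)
    .checkWindows(w)
    w
}

.checkWindows <- function(w) {
    stopifnot(all(w$start < w$end), all(w$count >= 0),
        all(w$gc >= 0 & w$gc <= 1),
        all(w$mappability >= 0 & w$mappability <= 1))
    invisible(w)
}

#' Correct windowed read counts for mappability and GC bias
#'
#' Windows below the mappability floor are discarded; remaining raw counts
#' are divided by mappability, then rescaled by the ratio of the global
#' autosomal median to the median of their GC-decile bin, so that the
#' systematic dependence of coverage on GC content is flattened:
#' `corrected = raw / map * globalMedian / binMedian`.  Bin medians are
#' computed from autosomal windows; bins with fewer than `minBinN`
#' autosomal windows fall back to the global median (no rescaling).  A
#' deterministic, loess-free correction validated by the slope-removal
#' property (post-correction regression of count on GC is flat).
#'
#' @param windows A window `data.frame` as from [readDepthWindows()] or
#'   [simulateWgsWindows()].
#' @param minMappability Exclusion threshold (default 0.8).
#' @param nBins Number of GC quantile bins (default 10, i.e. deciles).
#' @param minBinN Minimum autosomal windows per bin before falling back to
#'   the global median (default 20).
#' @return The retained windows with a `correctedCount` column appended.
#' @export
gcMappabilityCorrect <- function(windows, minMappability = 0.8,
                                 nBins = 10L, minBinN = 20L) {
    .checkWindows(windows)
    w <- windows[windows$mappability >= minMappability, , drop = FALSE]
    if (nrow(w) == 0L)
        stop("all windows excluded by the mappability filter")
    mc <- w$count / w$mappability
    auto <- w$chrom %in% as.character(1:22)
    if (!any(auto))
        stop("no autosomal windows available for normalisation")
    globalMed <- stats::median(mc[auto])
    if (globalMed == 0)
        stop("global autosomal median count is zero")
    brks <- unique(stats::quantile(w$gc, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(brks) < 2L) {
        # constant GC: nothing to flatten
        w$correctedCount <- mc
        return(w)
    }
    bin <- cut(w$gc, breaks = brks, include.lowest = TRUE)
    binMed <- vapply(levels(bin), function(b) {
        sel <- auto & bin == b
        if (sum(sel) < minBinN) globalMed else stats::median(mc[sel])
    }, numeric(1))
    binMed[binMed == 0] <- globalMed
    w$correctedCount <- mc * globalMed / binMed[as.integer(bin)]
    w
}

#' Chromosome-Y ploidy from corrected window counts
#'
#' Estimates the per-cell copy number of chromosome Y relative to the
#' diploid autosomal baseline: the per-copy depth is half the median
#' corrected autosomal count, and the Y ploidy is the median corrected
#' count over Y windows inside the male-specific region divided by that
#' per-copy depth.  Around 1 for a male without loss, between 0 and 1 under
#' LOY mosaicism, 0 for complete loss.  Median-based, so robust to a
#' minority of dropped-out Y windows; restriction to the MSY avoids
#' pseudo-autosomal windows whose copy number is carried by both sex
#' chromosomes.
#'
#' @param windows Corrected windows from [gcMappabilityCorrect()] (must
#'   carry `correctedCount`).
#' @param region MSY interval (1-based closed), see [msyRegion()].
#' @param minYWindows Minimum Y windows required (default 50).
#' @return A list: `chryPloidy`, `autosomalPerCopyDepth`, `nYWindowsUsed`,
#'   `nAutosomalWindowsUsed`.
#' @export
chrYPloidy <- function(windows, region = msyRegion(), minYWindows = 50L) {
    if (is.null(windows$correctedCount))
        stop("windows lack 'correctedCount'; run gcMappabilityCorrect() first")
    auto <- windows$chrom %in% as.character(1:22)
    # window [start, end) (0-based) vs closed 1-based MSY interval
    onY <- windows$chrom == "Y" &
        windows$end >= start(region)[1] & windows$start < end(region)[1]
    nY <- sum(onY)
    if (nY < minYWindows)
        stop(sprintf("only %d MSY windows available (minimum %d)",
            nY, minYWindows))
    if (!any(auto))
        stop("no autosomal windows available")
    perCopy <- stats::median(windows$correctedCount[auto]) / 2
    if (perCopy <= 0)
        stop("autosomal per-copy depth is non-positive")
    list(chryPloidy = stats::median(windows$correctedCount[onY]) / perCopy,
        autosomalPerCopyDepth = perCopy,
        nYWindowsUsed = nY,
        nAutosomalWindowsUsed = sum(auto))
}

#' LOY estimate from a chromosome-Y ploidy result
#'
#' Linear readout: percent of cells with Y is 100 times the Y ploidy and
#' LOY% its complement; ploidy above 1 yields negative LOY and, beyond the
#' shared tolerance, a gain-of-Y flag.
#'
#' @param ploidy A result list from [chrYPloidy()].
#' @param sampleId Sample identifier for the output record.
#' @param goyTolerance Percentage points of negative LOY tolerated before
#'   flagging apparent Y gain (default 2).
#' @return A one-row [S4Vectors::DataFrame] matching the unified estimate
#'   record: `sampleId`, `method = "wgs"`, `percentWithY`, `loyPercent`,
#'   `goyFlag`, plus window-count diagnostics.
#' @examples
#' p <- list(chryPloidy = 0.70, autosomalPerCopyDepth = 1000,
#'     nYWindowsUsed = 400, nAutosomalWindowsUsed = 4000)
#' loyFromPloidy(p, "s1")$loyPercent   # 30
#' @export
loyFromPloidy <- function(ploidy, sampleId = "sample", goyTolerance = 2) {
    pw <- 100 * ploidy$chryPloidy
    loy <- 100 - pw
    DataFrame(sampleId = sampleId, method = "wgs",
        percentWithY = pw, loyPercent = loy,
        goyFlag = loy < -goyTolerance,
        nYWindowsUsed = ploidy$nYWindowsUsed,
        nAutosomalWindowsUsed = ploidy$nAutosomalWindowsUsed)
}
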