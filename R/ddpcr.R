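#' Read a droplet-count table
#'
#' Reads a CSV of per-well droplet counts with columns `sample_id`,
#' `well_id`, `droplets_total`, `fam_positive` (AMELY channel),
#' `vic_positive` (AMELX channel); or, in pass-through mode, columns
#' `sample_id`, `well_id`, `ratio` holding pre-computed well ratios from
#' instrument software.
#'
#' @param path Path to the CSV.
#' @return A `data.frame` of wells; pass-through tables gain an attribute
#'   `ratioOnly = TRUE`.
#' @export
readDdpcrWells <- function(path) {
    w <- utils::read.csv(path, check.names = FALSE)
    if (all(c("sample_id", "well_id", "ratio") %in% colnames(w)) &&
        !"droplets_total" %in% colnames(w)) {
        attr(w, "ratioOnly") <- TRUE
        return(w)
    }
    need <- c("sample_id", "well_id", "droplets_total",
        "fam_positive", "vic_positive")
    miss <- setdiff(need, colnames(w))
    if (length(miss))
        stop("well table is missing required column(s): ",
            paste(miss, collapse = ", "))
    if (any(w$fam_positive > w$droplets_total) ||
        any(w$vic_positive > w$droplets_total))
        stop("positive droplet counts exceed total droplets")
    w
}

#' Poisson-corrected mean copies per droplet
#'
#' In droplet digital PCR each droplet may capture zero, one or several
#' template copies; the fraction of positive droplets therefore
#' under-represents the concentration, and the mean copies per droplet is
#' recovered from the zero class: `lambda = -ln(1 - positives/total)`.
#' A fully positive plate is saturated and has no finite estimate.
#'
#' @param positives Number of positive droplets (0 <= positives < total).
#' @param total Total accepted droplets (> 0).
#' @return Mean target copies per droplet.
#' @examples
#' poissonLambda(0, 15000)       # 0
#' poissonLambda(4500, 15000)    # -log(0.7)
#' @export
poissonLambda <- function(positives, total) {
    stopifnot(length(positives) == length(total))
    if (any(total <= 0))
        stop("'total' must be positive")
    if (any(positives < 0) || any(positives > total))
        stop("positive droplet count outside [0, total]")
    if (any(positives == total))
        stop("all droplets positive: concentration saturated, ratio undefined")
    -log1p(-positives / total)
}

#' AMELY/AMELX concentration ratio of one well
#'
#' Ratio of the Poisson-corrected concentrations of the FAM (AMELY, on
#' chromosome Y) and VIC (AMELX, on chromosome X) channels.  Droplet-volume
#' factors cancel, so the ratio is the per-cell Y:X gene dose: about 1 in
#' an unaffected male, below 1 under LOY mosaicism, 0 at complete loss.
#'
#' @param well A one-row `data.frame` (or list) with `droplets_total`,
#'   `fam_positive`, `vic_positive`.
#' @return The AMELY/AMELX ratio.
#' @examples
#' wellRatio(list(droplets_total = 15000,
#'     fam_positive = 3000, vic_positive = 3000))  # 1
#' @export
wellRatio <- function(well) {
    lamY <- poissonLambda(well$fam_positive, well$droplets_total)
    lamX <- poissonLambda(well$vic_positive, well$droplets_total)
    if (lamX == 0)
        stop("reference channel (AMELX/VIC) has zero concentration; ratio undefined")
    lamY / lamX
}

#' Aggregate duplicate wells and apply the re-run rule
#'
#' Samples are run in duplicate; per sample the well ratios are averaged
#' and their sample standard deviation (n - 1 denominator) computed when at
#' least two wells are present.  A sample whose ratio standard deviation
#' reaches the threshold (default 1.2, on the ratio scale as published) is
#' flagged for re-analysis rather than trusted.
#'
#' @param wells A well `data.frame` from [readDdpcrWells()] (droplet counts
#'   or pass-through ratios).
#' @param sdThreshold Re-run threshold on the ratio standard deviation
#'   (default 1.2; inclusive, "1.2 or higher").
#' @return A [S4Vectors::DataFrame], one row per sample: `sampleId`,
#'   `nWells`, `ratioMean`, `ratioSd` (`NA` for single wells), `rerunFlag`.
#' @examples
#' w <- data.frame(sample_id = "s", well_id = c("A1", "A2"),
#'     ratio = c(1.00, 1.01))
#' attr(w, "ratioOnly") <- TRUE
#' aggregateDuplicates(w)
#' @export
aggregateDuplicates <- function(wells, sdThreshold = 1.2) {
    if (isTRUE(attr(wells, "ratioOnly")) || "ratio" %in% colnames(wells)) {
        ratios <- wells$ratio
    } else {
        ratios <- vapply(seq_len(nrow(wells)),
            function(i) wellRatio(wells[i, ]), numeric(1))
    }
    ids <- unique(wells$sample_id)
    res <- lapply(ids, function(s) {
        r <- ratios[wells$sample_id == s]
        sdv <- if (length(r) >= 2L) stats::sd(r) else NA_real_
        DataFrame(sampleId = s, nWells = length(r),
            ratioMean = mean(r), ratioSd = sdv,
            rerunFlag = !is.na(sdv) && sdv >= sdThreshold)
    })
    do.call(rbind, res)
}

#' LOY estimate from an aggregated ddPCR ratio
#'
#' Linear readout: percent of cells with Y is 100 times the mean
#' AMELY/AMELX ratio and LOY% its complement.  Re-run-flagged samples are
#' withheld (`NA` estimate) unless explicitly overridden; ratios above 1
#' produce negative LOY and, beyond the shared tolerance, a gain-of-Y flag.
#'
#' @param result Aggregated table from [aggregateDuplicates()].
#' @param override Report estimates even for re-run-flagged samples
#'   (default `FALSE`).
#' @param goyTolerance Percentage points of negative LOY tolerated before
#'   flagging apparent Y gain (default 2).
#' @return A [S4Vectors::DataFrame] matching the unified estimate record:
#'   `sampleId`, `method = "ddpcr"`, `percentWithY`, `loyPercent`,
#'   `goyFlag`, `rerunFlag`.
#' @examples
#' r <- S4Vectors::DataFrame(sampleId = "s", nWells = 2L,
#'     ratioMean = 0.7, ratioSd = 0.01, rerunFlag = FALSE)
#' loyFromRatio(r)$loyPercent   # 30
#' @export
loyFromRatio <- function(result, override = FALSE, goyTolerance = 2) {
    usable <- override | !result$rerunFlag
    pw <- ifelse(usable, 100 * result$ratioMean, NA_real_)
    loy <- 100 - pw
    DataFrame(sampleId = result$sampleId, method = "ddpcr",
        percentWithY = pw, loyPercent = loy,
        goyFlag = !is.na(loy) & loy < -goyTolerance,
        rerunFlag = result$rerunFlag)
}
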