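#' Assemble per-subject LOY time series
#'
#' Joins per-sample LOY estimates to subject metadata (subject id and age
#' at draw) and orders each subject's measurements by age.  Samples whose
#' estimate was withheld (QC failure, ddPCR re-run) are dropped from the
#' series while the subject keeps its remaining points.  Duplicate
#' (subject, age) pairs and samples lacking metadata are errors, named
#' explicitly.
#'
#' @param estimates A unified estimate table (needs `sampleId`,
#'   `loyPercent`), e.g. from [estimateFromMLRRY()].
#' @param metadata A `data.frame` with `sampleId`, `subjectId`, `age`.
#' @return A `data.frame` with columns `subjectId`, `age`, `loyPercent`,
#'   `sampleId`, sorted by subject then age — one row per retained
#'   measurement.
#' @export
buildSeries <- function(estimates, metadata) {
    stopifnot(all(c("sampleId", "loyPercent") %in% colnames(estimates)),
        all(c("sampleId", "subjectId", "age") %in% colnames(metadata)))
    idx <- match(estimates$sampleId, metadata$sampleId)
    if (anyNA(idx))
        stop("no metadata for sample(s): ",
            paste(estimates$sampleId[is.na(idx)], collapse = ", "))
    ser <- data.frame(subjectId = metadata$subjectId[idx],
        age = metadata$age[idx],
        loyPercent = estimates$loyPercent,
        sampleId = estimates$sampleId,
        stringsAsFactors = FALSE)
    ser <- ser[!is.na(ser$loyPercent), , drop = FALSE]
    key <- paste(ser$subjectId, ser$age)
    if (anyDuplicated(key))
        stop("duplicate (subject, age) pairs: ",
            paste(unique(key[duplicated(key)]), collapse = "; "))
    ser[order(ser$subjectId, ser$age), , drop = FALSE]
}

#' Classify one subject's longitudinal LOY trajectory
#'
#' Serial sampling reveals strongly divergent clonal dynamics between men:
#' some show clear expansion of the LOY clone with age (progressors), in
#' others the cell fraction hardly changes, a few decline, and some follow
#' non-monotone patterns (rise then fall or the reverse).  The published
#' description names these patterns without an algorithm; this function
#' applies an explicit, deterministic rule set:
#'
#' * fewer than 2 points: `insufficient`;
#' * `complex`: at least 3 points and some pair of consecutive
#'   inter-visit changes has opposite signs with both magnitudes at least
#'   `deltaMin`;
#' * `progressor`: OLS slope of LOY% on age at least `slopeMin` *and* net
#'   change (last minus first) at least `deltaMin`;
#' * `decliner`: the mirror image;
#' * `stable` otherwise.
#'
#' Precedence: complex > progressor/decliner > stable.
#'
#' @param age Numeric vector of ages (years), strictly increasing.
#' @param loy Numeric vector of LOY percentages, parallel to `age`.
#' @param slopeMin Minimum |slope| in percentage points per year
#'   (default 0.75).
#' @param deltaMin Minimum |net change| in percentage points (default 5).
#' @return A list: `category`, `slope` (%/year, `NA` with < 2 points),
#'   `netChange`, `nPoints`.
#' @examples
#' classifyTrajectory(c(70, 78, 85), c(5, 22, 41))$category  # progressor
#' classifyTrajectory(c(70, 78, 85), c(5, 35, 12))$category  # complex
#' @export
classifyTrajectory <- function(age, loy, slopeMin = 0.75, deltaMin = 5) {
    stopifnot(length(age) == length(loy))
    n <- length(age)
    if (n < 2L)
        return(list(category = "insufficient", slope = NA_real_,
            netChange = if (n == 1L) 0 else NA_real_, nPoints = n))
    if (is.unsorted(age, strictly = TRUE))
        stop("'age' must be strictly increasing")
    slope <- stats::cov(age, loy) / stats::var(age)
    net <- loy[n] - loy[1]
    d <- diff(loy)
    complexCall <- n >= 3L && any(
        d[-length(d)] * d[-1] < 0 &
        abs(d[-length(d)]) >= deltaMin & abs(d[-1]) >= deltaMin)
    category <- if (complexCall) "complex"
        else if (slope >= slopeMin && net >= deltaMin) "progressor"
        else if (slope <= -slopeMin && net <= -deltaMin) "decliner"
        else "stable"
    list(category = category, slope = slope, netChange = net, nPoints = n)
}

#' Classify every subject in a series table
#'
#' Applies [classifyTrajectory()] to each subject of a series table from
#' [buildSeries()].  Deterministic and total: every subject receives
#' exactly one category, and the calls are invariant to input row order.
#'
#' @param series Series table from [buildSeries()].
#' @inheritParams classifyTrajectory
#' @return A `data.frame`, one row per subject: `subjectId`, `category`,
#'   `slope`, `netChange`, `nPoints`.
#' @export
classifyTrajectories <- function(series, slopeMin = 0.75, deltaMin = 5) {
    series <- series[order(series$subjectId, series$age), , drop = FALSE]
    ids <- unique(series$subjectId)
    rows <- lapply(ids, function(s) {
        sel <- series$subjectId == s
        cl <- classifyTrajectory(series$age[sel], series$loyPercent[sel],
            slopeMin = slopeMin, deltaMin = deltaMin)
        data.frame(subjectId = s, category = cl$category,
            slope = cl$slope, netChange = cl$netChange,
            nPoints = cl$nPoints, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Subjects reaching a high-LOY threshold at any time point
#'
#' Keeps subjects whose maximum LOY% across their serial measurements lies
#' on or above the threshold (inclusive), by default 30% — the level at
#' which at least 30% of nucleated blood cells lack the Y chromosome.
#'
#' @param series Series table from [buildSeries()].
#' @param threshold Percentage threshold in (0, 100); default 30.
#' @return The rows of `series` belonging to qualifying subjects.
#' @export
highLoySubset <- function(series, threshold = 30) {
    stopifnot(threshold > 0, threshold < 100)
    mx <- tapply(series$loyPercent, series$subjectId, max)
    keep <- names(mx)[mx >= threshold]
    series[series$subjectId %in% keep, , drop = FALSE]
}

#' Age association of a LOY readout by linear regression
#'
#' Ordinary least squares of the response (mLRRY or LOY%) on age across
#' all samples, with the standardized coefficient
#' `beta = b * sd(age) / sd(response)` — equal to the Pearson correlation
#' in simple regression — and a two-sided p-value from the t statistic.
#' Repeated measures are pooled, matching the simple published model; for
#' within-subject correlation a cluster-robust standard error is available
#' via `cluster` (sandwich estimator, clusters = subjects).
#'
#' @param age Numeric vector of ages.
#' @param response Numeric vector of the LOY readout, parallel to `age`.
#' @param responseName Label for the output record.
#' @param cluster Optional vector of subject ids for cluster-robust
#'   standard errors (requires the sandwich and lmtest packages).
#' @return A one-row `data.frame`: `response`, `predictor`, `b` (raw
#'   slope), `betaStd`, `pValue`, `n`.
#' @examples
#' a <- c(70, 75, 80, 85, 90)
#' ageAssociation(a, a)$betaStd   # 1
#' @export
ageAssociation <- function(age, response, responseName = "response",
                           cluster = NULL) {
    stopifnot(length(age) == length(response))
    ok <- is.finite(age) & is.finite(response)
    age <- age[ok]; response <- response[ok]
    if (length(age) < 3L)
        stop("need at least 3 complete observations")
    if (stats::sd(age) == 0 || stats::sd(response) == 0)
        stop("degenerate variance in age or response")
    fit <- stats::lm(response ~ age)
    b <- stats::coef(fit)[["age"]]
    if (is.null(cluster)) {
        p <- suppressWarnings(
            summary(fit)$coefficients["age", "Pr(>|t|)"])
    } else {
        if (!requireNamespace("sandwich", quietly = TRUE) ||
            !requireNamespace("lmtest", quietly = TRUE))
            stop("cluster-robust errors need the 'sandwich' and 'lmtest' packages")
        ct <- lmtest::coeftest(fit,
            vcov. = sandwich::vcovCL(fit, cluster = cluster[ok]))
        p <- ct["age", "Pr(>|t|)"]
    }
    data.frame(response = responseName, predictor = "age", b = b,
        betaStd = b * stats::sd(age) / stats::sd(response),
        pValue = p, n = length(age), stringsAsFactors = FALSE)
}

#' Squared Pearson correlation between two paired readouts
#'
#' Coefficient of determination of two matched measurement series (e.g.
#' sequencing-depth vs droplet-PCR LOY estimates of the same samples);
#' symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-degenerate.
#' @return Squared Pearson correlation in \[0, 1\].
#' @examples
#' pairwiseConcordance(1:10, 2 * (1:10) + 1)  # 1
#' @export
pairwiseConcordance <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
        stop("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in one of the readouts")
    stats::cor(x, y)^2
}
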