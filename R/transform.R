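#' Percentage of cells carrying a Y chromosome from mLRRY
#'
#' Evaluates the transformation `100 * 2^(2 * mLRRY)`: the array intensity
#' statistic, antiloged and squared to undo the intensity compression
#' established by power-law calibration against sequencing-depth and
#' droplet-PCR readouts (see [fitPowerCalibration()]).  Strictly increasing
#' in mLRRY, equal to 100 at mLRRY = 0, and unclamped: values above 100
#' (mosaic gain of Y) pass through.
#'
#' @param mlrry Finite numeric vector of (batch-corrected) mLRRY values.
#' @return Percentage of cells with a Y chromosome, same length as input.
#' @examples
#' percentWithYFromMLRRY(0)      # 100
#' percentWithYFromMLRRY(-0.5)   # 50
#' percentWithYFromMLRRY(-3.5)   # ~0.78, typical female range
#' @export
percentWithYFromMLRRY <- function(mlrry) {
    .assertFinite(mlrry, "mlrry")
    100 * 2^(2 * mlrry)
}

#' Percentage of cells with loss of chromosome Y from mLRRY
#'
#' Evaluates `100 * (1 - 2^(2 * mLRRY))`, the complement of
#' [percentWithYFromMLRRY()]: 0 at mLRRY = 0, approaching the theoretical
#' maximum of 100% as mLRRY decreases, and negative for positive mLRRY
#' (apparent mosaic gain of Y, GOY).  Negative values are reported, not
#' clamped; see [estimateFromMLRRY()] for optional clamping downstream.
#'
#' @inheritParams percentWithYFromMLRRY
#' @return LOY percentage, same length as input.
#' @examples
#' loyPercentFromMLRRY(0)               # 0
#' loyPercentFromMLRRY(-0.5)            # 50
#' loyPercentFromMLRRY(0.5 * log2(0.7)) # 30
#' @export
loyPercentFromMLRRY <- function(mlrry) {
    .assertFinite(mlrry, "mlrry")
    100 * (1 - 2^(2 * mlrry))
}

#' Invert the LOY-percentage transformation back to mLRRY
#'
#' Algebraic inverse of [loyPercentFromMLRRY()]:
#' `0.5 * log2(1 - loy/100)`.  Defined for LOY strictly below 100%
#' (complete loss maps to minus infinity).
#'
#' @param loy Numeric vector of LOY percentages, each < 100.
#' @return mLRRY values; round-trips with [loyPercentFromMLRRY()] to
#'   floating precision.
#' @examples
#' mlrryFromLoyPercent(50)  # -0.5
#' mlrryFromLoyPercent(75)  # -1
#' @export
mlrryFromLoyPercent <- function(loy) {
    .assertFinite(loy, "loy")
    if (any(loy >= 100))
        stop("'loy' must be < 100 (complete loss has no finite mLRRY)")
    0.5 * log2(1 - loy / 100)
}

#' Veitia's comparison formula for the LOY fraction
#'
#' Evaluates the previously published alternative
#' `F_LOY = 1.8 * (1 - 2^mLRR) + 0.015` on the fraction scale (multiply by
#' 100 for percentages).  Included for comparison: it agrees with
#' [loyPercentFromMLRRY()] near zero loss but exceeds 1 (i.e. 100%) for
#' strongly negative mLRR, with limit 1.815 as mLRR tends to minus
#' infinity, whereas the squared-antilog transformation stays within the
#' biologically possible range.
#'
#' @param mlrr Finite numeric vector of mLRR values.
#' @return Estimated LOY fraction (not percent).
#' @examples
#' veitiaLoyFraction(0)     # 0.015
#' veitiaLoyFraction(-3.5)  # ~1.66, above the 100% ceiling
#' @export
veitiaLoyFraction <- function(mlrr) {
    .assertFinite(mlrr, "mlrr")
    1.8 * (1 - 2^mlrr) + 0.015
}

#' Fit the power-law calibration between antiloged mLRRY and Y fraction
#'
#' Fits `y = a * (2^mLRRY)^b` relating the antiloged array statistic to the
#' Y-chromosome cell fraction measured by an orthogonal technology.  The
#' default route is ordinary least squares of `ln(y)` on `ln(2^mLRRY)`
#' (the log-log line whose slope is `b` and intercept `ln a`), with its
#' R-squared as fit diagnostic; `method = "nls"` refits on the natural
#' scale by nonlinear least squares started at the log-log solution (both
#' routes agree exactly on noiseless data).  Pairs with non-positive
#' measured fraction are excluded and counted.  The constants rounded to
#' the nearest integer define the closed-form transformation: a fit on
#' well-calibrated data yields (a, b) near (1, 2), hence
#' [loyPercentFromMLRRY()].
#'
#' @param mlrry Numeric vector of mLRRY values.
#' @param yFraction Numeric vector of measured fractions of cells with a
#'   Y chromosome (same length; values <= 0 are dropped).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return A [CalibrationFit-class].
#' @examples
#' g <- seq(-1, 0, by = 0.2)
#' fitPowerCalibration(g, 2^(2 * g))   # a = 1, b = 2, R^2 = 1
#' @export
fitPowerCalibration <- function(mlrry, yFraction,
                                method = c("loglog", "nls")) {
    method <- match.arg(method)
    stopifnot(length(mlrry) == length(yFraction))
    ok <- is.finite(mlrry) & is.finite(yFraction)
    nExcluded <- sum(ok & yFraction <= 0)
    ok <- ok & yFraction > 0
    x <- mlrry[ok]; y <- yFraction[ok]
    if (length(x) < 3L)
        stop("need at least 3 usable pairs (y > 0) to fit the calibration")
    if (stats::sd(x) == 0)
        stop("zero variance in mLRRY; calibration is unidentifiable")
    lx <- x * log(2)          # ln(2^mlrry)
    fit <- stats::lm(log(y) ~ lx)
    a <- exp(stats::coef(fit)[[1]])
    b <- stats::coef(fit)[[2]]
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (method == "nls") {
        # start at the log-log solution; tolerate the zero-residual case
        nfit <- stats::nls(y ~ a * (2^x)^b, start = list(a = a, b = b),
            control = stats::nls.control(maxiter = 200, warnOnly = TRUE,
                scaleOffset = 1))
        a <- stats::coef(nfit)[["a"]]
        b <- stats::coef(nfit)[["b"]]
        r2 <- 1 - sum(stats::resid(nfit)^2) / sum((y - mean(y))^2)
    }
    new("CalibrationFit", a = a, b = b,
        aRounded = as.integer(.roundHalfAway(a)),
        bRounded = as.integer(.roundHalfAway(b)),
        rSquared = min(r2, 1), n = length(x),
        nExcluded = as.integer(nExcluded), method = method)
}

#' Accessors for CalibrationFit
#'
#' @param object A [CalibrationFit-class].
#' @return `calibrationConstants()` returns the fitted `c(a=, b=)`;
#'   `roundedConstants()` the integer-rounded pair; `calibrationR2()` the
#'   log-log R-squared.
#' @export
calibrationConstants <- function(object) {
    stopifnot(is(object, "CalibrationFit"))
    c(a = object@a, b = object@b)
}

#' @rdname calibrationConstants
#' @export
roundedConstants <- function(object) {
    stopifnot(is(object, "CalibrationFit"))
    c(a = object@aRounded, b = object@bRounded)
}

#' @rdname calibrationConstants
#' @export
calibrationR2 <- function(object) {
    stopifnot(is(object, "CalibrationFit"))
    object@rSquared
}

#' LOY estimates from a QC'd mLRRY table
#'
#' Converts per-sample mLRRY values (batch-corrected where available) into
#' the unified LOY-estimate record: percent of cells with Y, LOY%, and a
#' gain-of-Y flag raised when LOY% falls below `-goyTolerance`.  Estimates
#' for QC-failed samples are withheld (`NA`) with the failure reasons
#' carried through rather than dropped.
#'
#' @param mlrry A table from [qcSamples()] /
#'   [correctBatchEffects()].
#' @param useCorrected Use `mlrryCorrected` when present (default), else
#'   the raw value.
#' @param goyTolerance Percentage points of negative LOY tolerated before
#'   flagging apparent Y gain (default 2).
#' @param clamp Clamp LOY% into \[0, 100\] (default `FALSE`: sub-zero
#'   observations are genuine data states).
#' @return A [S4Vectors::DataFrame]: `sampleId`, `method = "array"`,
#'   `mlrry`, `percentWithY`, `loyPercent`, `goyFlag`, `qcPass`,
#'   `qcReasons`.
#' @export
estimateFromMLRRY <- function(mlrry, useCorrected = TRUE,
                              goyTolerance = 2, clamp = FALSE) {
    stopifnot("mlrryRaw" %in% colnames(mlrry))
    val <- if (useCorrected && "mlrryCorrected" %in% colnames(mlrry))
        mlrry$mlrryCorrected else mlrry$mlrryRaw
    qcPass <- if ("qcPass" %in% colnames(mlrry)) mlrry$qcPass
        else rep(TRUE, nrow(mlrry))
    usable <- qcPass & is.finite(val)
    pw <- ifelse(usable, 100 * 2^(2 * val), NA_real_)
    loy <- 100 - pw
    goy <- !is.na(loy) & loy < -goyTolerance
    if (clamp)
        loy <- pmin(pmax(loy, 0), 100)
    DataFrame(sampleId = mlrry$sampleId,
        method = "array",
        mlrry = val,
        percentWithY = pw,
        loyPercent = loy,
        goyFlag = goy,
        qcPass = qcPass,
        qcReasons = if ("qcReasons" %in% colnames(mlrry))
            mlrry$qcReasons else "")
}
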