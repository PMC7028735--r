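test_that("transformation formulas evaluate to their closed-form values", {
    expect_equal(percentWithYFromMLRRY(0), 100)
    expect_equal(percentWithYFromMLRRY(-0.5), 50)
    expect_equal(percentWithYFromMLRRY(-3.5), 0.78125)  # female range
    expect_equal(loyPercentFromMLRRY(0), 0)
    expect_equal(loyPercentFromMLRRY(-0.5), 50)
    expect_equal(loyPercentFromMLRRY(0.5 * log2(0.7)), 30)
    expect_equal(loyPercentFromMLRRY(0.05), 100 * (1 - 2^0.1))  # < 0, gain
    expect_error(percentWithYFromMLRRY(NaN), "finite")
    expect_error(loyPercentFromMLRRY(Inf), "finite")
})

test_that("the inverse transformation round-trips and rejects loy >= 100", {
    expect_equal(mlrryFromLoyPercent(0), 0)
    expect_equal(mlrryFromLoyPercent(50), -0.5)
    expect_equal(mlrryFromLoyPercent(75), -1)
    g <- seq(-4, 0.2, by = 0.01)
    expect_equal(mlrryFromLoyPercent(loyPercentFromMLRRY(g)), g,
        tolerance = 1e-9)
    expect_error(mlrryFromLoyPercent(100), "< 100")
})

test_that("complementarity and monotonicity hold across the domain", {
    g <- seq(-6, 1, by = 0.05)
    expect_equal(loyPercentFromMLRRY(g) + percentWithYFromMLRRY(g),
        rep(100, length(g)))
    expect_true(all(diff(loyPercentFromMLRRY(g)) < 0))   # strictly decreasing
    expect_true(all(loyPercentFromMLRRY(g) < 100))       # supremum 100
    expect_gt(loyPercentFromMLRRY(-20), 100 - 1e-9)
})

test_that("the comparison formula matches its constants and exceeds 100%", {
    expect_equal(veitiaLoyFraction(0), 0.015)
    expect_equal(veitiaLoyFraction(-3.5), 1.8 * (1 - 2^-3.5) + 0.015)
    expect_gt(veitiaLoyFraction(-3.5), 1)        # overestimation regime
    expect_equal(veitiaLoyFraction(-1e6), 1.815) # limit as mLRR -> -Inf
    # dominance: never below the squared-antilog transform for losses,
    # near-equality at low LOY
    g <- seq(-4, 0, by = 0.01)
    expect_true(all(100 * veitiaLoyFraction(g) >=
        loyPercentFromMLRRY(g) - 1e-9))
    low <- seq(-0.05, 0, by = 0.005)
    expect_true(all(abs(100 * veitiaLoyFraction(low) -
        loyPercentFromMLRRY(low)) < 3))
})

test_that("power calibration recovers (1, 2) exactly on noiseless data", {
    g <- seq(-1, 0, by = 0.2)
    fit <- fitPowerCalibration(g, 2^(2 * g))
    expect_equal(calibrationConstants(fit), c(a = 1, b = 2),
        tolerance = 1e-9)
    expect_equal(calibrationR2(fit), 1, tolerance = 1e-12)
    expect_equal(roundedConstants(fit), c(a = 1L, b = 2L))
    # both fitting routes agree on noiseless data
    nls <- fitPowerCalibration(g, 2^(2 * g), method = "nls")
    expect_equal(calibrationConstants(nls), c(a = 1, b = 2),
        tolerance = 1e-6)
})

test_that("published-scale constants round half away from zero to (1, 2)", {
    g <- seq(-1, 0, by = 0.1)
    fit <- fitPowerCalibration(g, 0.9242 * (2^g)^1.7703)
    expect_equal(unname(calibrationConstants(fit)), c(0.9242, 1.7703),
        tolerance = 1e-6)
    expect_equal(roundedConstants(fit), c(a = 1L, b = 2L))
})

test_that("exponent recovery under multiplicative noise stays in the envelope", {
    g <- rep(seq(-1, 0, by = 0.2), 4)
    set.seed(1)
    fit <- fitPowerCalibration(g, 2^(2 * g) * exp(rnorm(length(g), 0, 0.05)))
    b <- calibrationConstants(fit)[["b"]]
    expect_gt(b, 1.7); expect_lt(b, 2.3)
})

test_that("the log-log estimator of the exponent is unbiased", {
    g <- rep(seq(-1, 0, by = 0.1), 3)
    set.seed(99)
    bs <- replicate(200, {
        y <- 2^(2 * g) * exp(rnorm(length(g), 0, 0.05))
        calibrationConstants(fitPowerCalibration(g, y))[["b"]]
    })
    expect_lt(abs(mean(bs) - 2), 0.05)
})

test_that("calibration fitting validates its inputs", {
    expect_error(fitPowerCalibration(c(0, -1), c(1, 0.25)), "at least 3")
    expect_error(fitPowerCalibration(rep(-0.5, 5), rep(0.5, 5)),
        "zero variance")
    # non-positive fractions excluded and counted
    fit <- fitPowerCalibration(c(-1, -0.5, -0.2, 0, -2),
        c(0.25, 0.5, 0.75, 1, -0.1))
    expect_equal(fit@nExcluded, 1L)
    expect_equal(fit@n, 4L)
})

test_that("estimateFromMLRRY fills the unified record and flags gain of Y", {
    tbl <- S4Vectors::DataFrame(
        sampleId = c("a", "b", "c", "d"),
        batchId = "b1",
        mlrryRaw = c(0, -0.5, 0.1, -0.2),
        mlrryCorrected = c(0, -0.5, 0.1, NA),
        qcPass = c(TRUE, TRUE, TRUE, FALSE),
        qcReasons = c("", "", "", "max_lrr_sd"))
    est <- estimateFromMLRRY(tbl)
    expect_equal(est$loyPercent[1], 0)
    expect_false(est$goyFlag[1])
    expect_equal(est$loyPercent[2], 50)
    expect_equal(est$loyPercent[3], 100 * (1 - 2^0.2))  # about -14.9
    expect_true(est$goyFlag[3])
    expect_true(is.na(est$loyPercent[4]))               # withheld, not dropped
    expect_equal(est$qcReasons[4], "max_lrr_sd")
    expect_equal(est$loyPercent + est$percentWithY,
        ifelse(est$qcPass, 100, NA_real_))
    # clamping is opt-in
    cl <- estimateFromMLRRY(tbl, clamp = TRUE)
    expect_equal(cl$loyPercent[3], 0)
    expect_true(cl$goyFlag[3])  # flag raised before clamping
})
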