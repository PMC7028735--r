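test_that("mLRRY is the sample median of MSY LRR values", {
    expect_equal(computeMLRRY(c(-0.2, 0, -0.4), minProbes = 1), -0.2)
    expect_equal(computeMLRRY(c(-0.2, 0, -0.4, 5.0), minProbes = 1), -0.1)
    expect_equal(computeMLRRY(c(-0.3, -0.3, -0.3), minProbes = 1), -0.3)
    expect_true(is.na(computeMLRRY(rnorm(50), minProbes = 100)))
    # NA removal happens before the probe-count check
    expect_true(is.na(computeMLRRY(c(rnorm(99), NA), minProbes = 100)))
})

test_that("median resists outlier contamination better than the mean", {
    set.seed(42)
    for (i in 1:20) {
        x <- rnorm(500, -0.2, 0.15)
        y <- x
        y[1:50] <- y[1:50] + 2.0    # 10% contamination
        dMed <- abs(computeMLRRY(y) - computeMLRRY(x))
        dMean <- abs(mean(y) - mean(x))
        expect_lt(dMed, dMean)
    }
})

test_that("QC criteria are applied per sample without dropping any", {
    set.seed(7)
    clean <- simulateArray(0.9, nMsyProbes = 300, nAutosomalProbes = 200,
        probeNoiseSd = 0.15, seed = 1, sampleId = "clean")
    qc <- qcSamples(clean, minProbes = 100)
    expect_true(qc$qcPass)
    expect_equal(qc$qcReasons, "")
    expect_equal(qc$nMsyProbes, 300L)

    few <- simulateArray(0.9, nMsyProbes = 50, nAutosomalProbes = 200,
        seed = 2, sampleId = "few")
    qcf <- qcSamples(few, minProbes = 100)
    expect_false(qcf$qcPass)
    expect_match(qcf$qcReasons, "min_probes")
    expect_true(is.na(qcf$mlrryRaw))

    noisy <- simulateArray(0.9, nMsyProbes = 300, nAutosomalProbes = 200,
        probeNoiseSd = 0.9, seed = 3, sampleId = "noisy")
    qcn <- qcSamples(noisy)
    expect_false(qcn$qcPass)
    expect_match(qcn$qcReasons, "max_lrr_sd")

    # conservation: every input sample appears exactly once
    both <- cbind(SummarizedExperiment::assay(clean),
        SummarizedExperiment::assay(noisy))
    x2 <- ArrayLRRSet(both, SummarizedExperiment::rowRanges(clean),
        data.frame(sampleId = c("clean", "noisy")))
    qc2 <- qcSamples(x2)
    expect_equal(nrow(qc2), 2L)
    expect_equal(sum(qc2$qcPass) + sum(!qc2$qcPass), 2L)
})

test_that("missingness above the threshold fails QC", {
    gr <- GenomicRanges::GRanges(
        c(rep("1", 100), rep("Y", 150)),
        IRanges::IRanges(c(1:100 * 1000L, 2781480L + 1:150 * 100L),
            width = 1),
        probeId = sprintf("p%03d", 1:250))
    lrr <- matrix(rnorm(250, 0, 0.1), ncol = 1,
        dimnames = list(NULL, "s1"))
    lrr[1:30] <- NA    # 12% missing
    x <- ArrayLRRSet(lrr, gr, data.frame(sampleId = "s1"))
    qc <- qcSamples(x, minProbes = 100, maxMissing = 0.05)
    expect_match(qc$qcReasons, "max_missing")
})

test_that("kernel-density mode recovers the batch centre", {
    set.seed(11)
    x <- rnorm(500, -0.30, 0.05)
    est <- estimateBatchMode(x)
    # independent oracle: histogram argmax at fine binning
    h <- hist(x, breaks = seq(min(x) - 0.01, max(x) + 0.01, by = 0.005),
        plot = FALSE)
    oracle <- h$mids[which.max(h$counts)]
    expect_lt(abs(est$mode - (-0.30)), 0.02)
    expect_lt(abs(est$mode - oracle), 0.02)
    expect_equal(est$n, 500L)
    expect_gt(est$bandwidth, 0)
})

test_that("degenerate and mixture distributions give sensible modes", {
    expect_equal(estimateBatchMode(rep(0, 30))$mode, 0)
    set.seed(12)
    mix <- c(rnorm(400, 0, 0.05), rnorm(100, -0.8, 0.05))
    expect_lt(abs(estimateBatchMode(mix)$mode), 0.05)  # not in the LOY tail
    expect_warning(expect_null(estimateBatchMode(rnorm(10))), "unavailable")
})

test_that("batch correction subtracts the mode and keeps raw values", {
    res <- S4Vectors::DataFrame(sampleId = "s", batchId = "b",
        mlrryRaw = -0.35, qcPass = TRUE)
    out <- applyBatchCorrection(res, list(mode = -0.30, batchId = "b"))
    expect_equal(out$mlrryCorrected, -0.05)
    expect_equal(out$mlrryRaw, -0.35)
    out2 <- applyBatchCorrection(res, list(mode = -0.35, batchId = "b"))
    expect_equal(out2$mlrryCorrected, 0)
    expect_error(
        applyBatchCorrection(res, list(mode = 0, batchId = "other")),
        "batch mismatch.*other")
})

test_that("batch correction is location-equivariant and re-centres batches", {
    set.seed(13)
    raw <- rnorm(200, 0, 0.03) - 0.01 * rexp(200)  # non-LOY heavy cohort
    tbl <- S4Vectors::DataFrame(sampleId = sprintf("s%03d", 1:200),
        batchId = "b1", mlrryRaw = raw + 0.25, qcPass = TRUE)
    corr <- correctBatchEffects(tbl)
    # post-correction mode sits at zero
    est <- estimateBatchMode(corr$mlrryCorrected)
    expect_lt(abs(est$mode), 0.02)
    # adding a constant to the whole batch leaves corrected values unchanged
    tbl2 <- tbl; tbl2$mlrryRaw <- tbl$mlrryRaw + 0.5
    corr2 <- correctBatchEffects(tbl2)
    expect_equal(corr2$mlrryCorrected, corr$mlrryCorrected,
        tolerance = 1e-6)
})

test_that("small batches keep raw values with a flag", {
    tbl <- S4Vectors::DataFrame(sampleId = sprintf("s%d", 1:10),
        batchId = "tiny", mlrryRaw = rnorm(10), qcPass = TRUE)
    expect_warning(out <- correctBatchEffects(tbl), "below minimum size")
    expect_false(any(out$batchCorrected))
    expect_equal(out$mlrryCorrected, out$mlrryRaw)
})
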