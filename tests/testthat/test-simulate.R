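test_that("trajectory archetypes have their defining shapes", {
    ages <- seq(70, 85, by = 5)
    expect_equal(simulateTrajectory("stable", ages, seed = 1,
        jitterSd = 0), rep(simulateTrajectory("stable", ages, seed = 1,
        jitterSd = 0)[1], 4))
    w <- simulateTrajectory("progressor", ages, seed = 2)
    expect_true(all(diff(w) < 0))    # fraction-with-Y strictly decreasing
    wd <- simulateTrajectory("decliner", ages, seed = 3)
    expect_true(all(diff(wd) > 0))
    wc <- simulateTrajectory("complex", ages, seed = 4)
    expect_true(any(diff(wc) > 0) && any(diff(wc) < 0))
    expect_error(simulateTrajectory("complex", c(70, 80), seed = 5),
        "at least 3")
    expect_error(simulateTrajectory("mystery", ages, seed = 6), "unknown")
    # determinism
    expect_identical(simulateTrajectory("progressor", ages, seed = 7),
        simulateTrajectory("progressor", ages, seed = 7))
    # gain-of-Y baseline passes through, bounded at 1.1
    wg <- simulateTrajectory("stable", ages, seed = 8, baseW = 1.05)
    expect_true(all(wg > 1) && all(wg <= 1.1))
})

test_that("noiseless arrays reproduce the compression model exactly", {
    expect_equal(computeMLRRY(simulateArray(1, probeNoiseSd = 0,
        seed = 1)), c(sim1 = 0))
    expect_equal(computeMLRRY(simulateArray(0.25, probeNoiseSd = 0,
        seed = 2)), c(sim1 = -1))
    off <- simulateArray(0.5, probeNoiseSd = 0, batchOffset = 0.1,
        seed = 3)
    expect_equal(unname(computeMLRRY(off)), -0.4)
    expect_error(simulateArray(0), "0, 1.1")
})

test_that("simulated probes fall on the right sides of the MSY boundary", {
    x <- simulateArray(0.5, nMsyProbes = 300, nAutosomalProbes = 200,
        seed = 4)
    gr <- SummarizedExperiment::rowRanges(x)
    y <- gr[as.character(GenomicRanges::seqnames(gr)) == "Y"]
    expect_equal(length(y), 300L)
    expect_true(all(GenomicRanges::start(y) >= 2781480 &
        GenomicRanges::start(y) <= 56887902))
    expect_equal(length(SummarizedExperiment::rowRanges(
        selectMSYProbes(x))), 300L)
})

test_that("array pathway recovers the simulated LOY level", {
    set.seed(51)
    est <- replicate(200, simulateMsyLoyEstimate(0.7))
    expect_lt(abs(mean(est) - 30), 1)
})

test_that("sequencing windows recover ploidy with and without GC bias", {
    p1 <- chrYPloidy(gcMappabilityCorrect(
        simulateWgsWindows(1, seed = 52)))$chryPloidy
    expect_lt(abs(p1 - 1), 0.02)
    w0 <- simulateWgsWindows(0, seed = 53)
    expect_true(all(w0$count[w0$chrom == "Y"] == 0))
    expect_equal(chrYPloidy(gcMappabilityCorrect(w0))$chryPloidy, 0)
    # GC bias inflates the estimate's error unless corrected
    wb <- simulateWgsWindows(0.7, gcBiasCoeff = 0.8, seed = 54)
    uncorr <- wb
    uncorr$correctedCount <- uncorr$count / uncorr$mappability
    uncorr <- uncorr[uncorr$mappability >= 0.8, ]
    pCorr <- chrYPloidy(gcMappabilityCorrect(wb))$chryPloidy
    expect_lt(abs(pCorr - 0.7), 0.03)
})

test_that("ddPCR wells are binomial with the right means and deterministic", {
    set.seed(55)
    r1 <- mean(replicate(300, wellRatio(simulateDdpcrWell(1))))
    expect_lt(abs(r1 - 1), 0.01)
    w0 <- simulateDdpcrWell(0, seed = 56)
    expect_equal(w0$fam_positive, 0L)
    expect_identical(simulateDdpcrWell(0.7, seed = 57),
        simulateDdpcrWell(0.7, seed = 57))
})

test_that("the default cohort reproduces the study scale", {
    co <- simulateCohort(seed = 61)
    expect_equal(nrow(co$metadata), 798L)
    expect_equal(length(unique(co$metadata$subjectId)), 276L)
    expect_equal(nrow(co$truth), 798L)
    expect_true(all(co$metadata$age >= 70 & co$metadata$age <= 93))
    spans <- tapply(co$metadata$age, co$metadata$subjectId,
        function(a) diff(range(a)))
    expect_true(all(spans <= 22.2 + 1e-9))
    draws <- table(co$metadata$subjectId)
    expect_true(all(draws >= 2 & draws <= 5))
    expect_true(all(co$truth$trueFractionWithY >= 0 &
        co$truth$trueFractionWithY <= 1.1))
    # pairwise-technology subsets mirror the study design
    expect_equal(length(unique(co$ddpcrWells$sample_id)), 121L)
    expect_equal(length(unique(co$wgsWindows$sample_id)), 26L)
    expect_true(all(unique(co$wgsWindows$sample_id) %in%
        co$ddpcrWells$sample_id))
})

test_that("single-subject bundles are valid and cohort seeding is exact", {
    tiny <- simulateCohort(nSubjects = 1, nSamples = 1,
        drawsRange = c(1L, 1L), archetypeMix = c(progressor = 0,
            stable = 1, decliner = 0, complex = 0),
        ddpcrN = 1, wgsN = 1, nAutosomalWindows = 100, nYWindows = 60,
        seed = 62)
    expect_equal(nrow(tiny$metadata), 1L)
    co1 <- simulateCohort(nSubjects = 20, nSamples = 60, seed = 63,
        ddpcrN = 4, wgsN = 2, nAutosomalWindows = 100, nYWindows = 60)
    co2 <- simulateCohort(nSubjects = 20, nSamples = 60, seed = 63,
        ddpcrN = 4, wgsN = 2, nAutosomalWindows = 100, nYWindows = 60)
    expect_identical(co1$truth, co2$truth)
    expect_identical(SummarizedExperiment::assay(co1$lrr),
        SummarizedExperiment::assay(co2$lrr))
    expect_identical(co1$ddpcrWells, co2$ddpcrWells)
    expect_error(simulateCohort(nSubjects = 10, nSamples = 5, seed = 1),
        "infeasible")
    expect_error(simulateCohort(maxSpan = 5, seed = 1), "infeasible")
})

test_that("written cohort files round-trip through every reader", {
    co <- simulateCohort(nSubjects = 6, nSamples = 15, seed = 64,
        nMsyProbes = 150, nAutosomalProbes = 100,
        ddpcrN = 3, wgsN = 2, nAutosomalWindows = 200, nYWindows = 60)
    dir <- tempfile("cohort")
    paths <- writeCohort(co, dir)
    expect_true(all(file.exists(paths)))
    x <- readLRRReport(paths["report"], paths["manifest"])
    expect_equal(dim(x), c(250L, 15L))
    expect_equal(sort(SummarizedExperiment::colData(x)$sampleId),
        sort(co$metadata$sampleId))
    wells <- readDdpcrWells(paths["wells"])
    expect_equal(nrow(wells), nrow(co$ddpcrWells))
    win <- readDepthWindows(paths["windows"])
    expect_equal(nrow(win), nrow(co$wgsWindows))
    # byte-identical rewrite under the same seed
    co2 <- simulateCohort(nSubjects = 6, nSamples = 15, seed = 64,
        nMsyProbes = 150, nAutosomalProbes = 100,
        ddpcrN = 3, wgsN = 2, nAutosomalWindows = 200, nYWindows = 60)
    dir2 <- tempfile("cohort2")
    paths2 <- writeCohort(co2, dir2)
    for (f in names(paths))
        expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
})

test_that("end-to-end recovery is linear across the default cohort", {
    co <- simulateCohort(seed = 65, ddpcrN = 10, wgsN = 3,
        nAutosomalWindows = 100, nYWindows = 60)
    qc <- qcSamples(co$lrr)
    est <- estimateFromMLRRY(suppressWarnings(correctBatchEffects(qc)))
    truthLoy <- 100 * (1 - co$truth$trueFractionWithY[
        match(est$sampleId, co$truth$sampleId)])
    fit <- lm(est$loyPercent ~ truthLoy)
    expect_gt(coef(fit)[2], 0.95); expect_lt(coef(fit)[2], 1.05)
    expect_gt(coef(fit)[1], -2); expect_lt(coef(fit)[1], 2)
})
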