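# Synthetic-data generators. Each pathway generator emits ground truth next
# to the observation so every estimator is testable by parameter recovery;
# the array model embeds the factor-2 intensity compression under which the
# published calibration is exact (mLRRY = 0.5 * log2(fraction-with-Y)).

# monotone scaled logistic through (t1, from) and (tn, to)
.scaledLogistic <- function(t, from, to, rate) {
    g <- stats::plogis(rate * (t - mean(range(t))))
    g <- (g - g[1]) / (g[length(g)] - g[1])
    from + (to - from) * g
}

#' Simulate a subject's true LOY trajectory
#'
#' Generates the latent fraction of cells still carrying a Y chromosome at
#' each sampling age, under one of four clonal archetypes observed in
#' serially sampled men:
#' * `progressor` — non-linear (logistic) expansion of the LOY clone, so
#'   the fraction-with-Y decreases strictly and the net loss scales with
#'   the follow-up span (at least 8 percentage points);
#' * `stable` — constant fraction plus small Gaussian jitter;
#' * `decliner` — monotone shrinkage of the LOY clone;
#' * `complex` — rise-then-fall or fall-then-reverse, with every
#'   inter-visit change of the affected phase at least 8 points (requires
#'   at least 3 ages).
#'
#' Fractions are clipped to \[0.02, 1.1\]; values above 1 represent mosaic
#' gain of Y and arise only when `baseW > 1` is supplied for a stable
#' subject.
#'
#' @param archetype One of `"progressor"`, `"stable"`, `"decliner"`,
#'   `"complex"`.
#' @param ages Sorted numeric vector of sampling ages (years).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   trajectory exactly.
#' @param baseW Baseline fraction-with-Y for stable subjects (default
#'   drawn; supply > 1 to simulate gain of Y).
#' @param jitterSd Jitter of the stable archetype on the fraction scale
#'   (default 0.01; 0 gives a constant trajectory).
#' @return Numeric vector of true fractions-with-Y, parallel to `ages`.
#' @examples
#' simulateTrajectory("stable", c(70, 80, 90), seed = 1, jitterSd = 0)
#' @export
simulateTrajectory <- function(archetype, ages, seed = NULL,
                               baseW = NULL, jitterSd = 0.01) {
    .setSeed(seed)
    if (is.unsorted(ages))
        stop("'ages' must be sorted")
    n <- length(ages)
    span <- if (n > 1L) ages[n] - ages[1] else 0
    l <- switch(archetype,
        progressor = {
            l1 <- stats::runif(1, 0, 0.10)
            delta <- min(0.95 - l1,
                max(0.08, stats::runif(1, 0.015, 0.035) * span))
            .scaledLogistic(ages, l1, l1 + delta, stats::runif(1, 0.2, 0.6))
        },
        decliner = {
            delta <- max(0.08, stats::runif(1, 0.015, 0.035) * span)
            l1 <- min(0.9, delta + stats::runif(1, 0.02, 0.3))
            .scaledLogistic(ages, l1, l1 - delta, stats::runif(1, 0.2, 0.6))
        },
        stable = {
            w0 <- if (!is.null(baseW)) baseW
                else if (stats::runif(1) < 0.7) 1 - stats::runif(1, 0, 0.02)
                else 1 - stats::runif(1, 0.05, 0.25)
            return(pmin(pmax(w0 + stats::rnorm(n, 0, jitterSd), 0.02), 1.1))
        },
        complex = {
            if (n < 3L)
                stop("'complex' archetype requires at least 3 ages")
            turn <- if (n == 3L) 2L else sample(2:(n - 1L), 1)
            up <- stats::runif(turn - 1L, 0.08, 0.2)
            down <- stats::runif(n - turn, 0.08, 0.2)
            if (stats::runif(1) < 0.5) {      # rise then fall
                l1 <- stats::runif(1, 0.02, 0.1)
                if (l1 + sum(up) > 0.95)
                    up <- up * (0.95 - l1) / sum(up)
                l1 + cumsum(c(0, up, -down))
            } else {                          # fall then reverse
                l1 <- min(0.9, sum(up) + stats::runif(1, 0.02, 0.1))
                l1 + cumsum(c(0, -up, down))
            }
        },
        stop("unknown archetype: ", archetype))
    pmin(pmax(1 - l, 0.02), 1.1)
}

#' Simulate one SNP-array sample at a known LOY fraction
#'
#' Draws per-probe LRR values under the generative inverse of the
#' calibration: MSY probes are Normal with mean
#' `0.5 * log2(w) + batchOffset` (the factor-2 intensity compression) and
#' autosomal probes Normal with mean 0, both with standard deviation
#' `probeNoiseSd`.  The expected mLRRY of the output is therefore
#' `0.5 * log2(w) + batchOffset` exactly.  Probe coordinates are drawn
#' inside the MSY for Y probes and across chromosomes 1-22 otherwise.
#'
#' @param w True fraction of cells with a Y chromosome, in (0, 1.1\].
#' @param nMsyProbes,nAutosomalProbes Probe counts (defaults 1200 / 2000).
#' @param probeNoiseSd Per-probe LRR noise (log2 units, default 0.15).
#' @param batchOffset Technical shift of the MSY probe means (default 0).
#' @param seed Optional integer seed.
#' @param sampleId,subjectId,batchId Identifiers for the output.
#' @param region MSY interval for probe placement.
#' @return An [ArrayLRRSet-class] with one sample; the truth is stored in
#'   `metadata()$truth`.
#' @examples
#' x <- simulateArray(0.25, probeNoiseSd = 0, seed = 1)
#' computeMLRRY(x)  # exactly -1
#' @export
simulateArray <- function(w, nMsyProbes = 1200L, nAutosomalProbes = 2000L,
                          probeNoiseSd = 0.15, batchOffset = 0,
                          seed = NULL, sampleId = "sim1",
                          subjectId = sampleId, batchId = "batch1",
                          region = msyRegion()) {
    if (!is.numeric(w) || length(w) != 1L || w <= 0 || w > 1.1)
        stop("'w' must lie in (0, 1.1]; for female samples simulate w near 0.08")
    .setSeed(seed)
    width <- end(region)[1] - start(region)[1] + 1L
    msyPos <- sort(sample.int(width, nMsyProbes)) + start(region)[1] - 1L
    autoChrom <- sort(sample(as.character(1:22), nAutosomalProbes,
        replace = TRUE))
    autoPos <- sample.int(2.4e8, nAutosomalProbes, replace = TRUE)
    gr <- GRanges(c(autoChrom, rep("Y", nMsyProbes)),
        IRanges(c(autoPos, msyPos), width = 1),
        probeId = c(sprintf("auto_%05d", seq_len(nAutosomalProbes)),
            sprintf("msy_%05d", seq_len(nMsyProbes))))
    lrr <- c(stats::rnorm(nAutosomalProbes, 0, probeNoiseSd),
        stats::rnorm(nMsyProbes, 0.5 * log2(w) + batchOffset, probeNoiseSd))
    obj <- ArrayLRRSet(matrix(lrr, ncol = 1,
            dimnames = list(NULL, sampleId)), gr,
        DataFrame(sampleId = sampleId, subjectId = subjectId,
            batchId = batchId))
    metadata(obj)$truth <- data.frame(sampleId = sampleId,
        trueFractionWithY = w, batchOffset = batchOffset)
    obj
}

#' Simulate windowed sequencing read counts at a known LOY fraction
#'
#' Poisson window counts at 30x-equivalent depth: the per-haploid-copy mean
#' count is `depth * windowSize / readLength / 2`; autosomal windows draw
#' from Poisson at twice that mean and MSY windows at `w` times it, both
#' modulated by a linear GC bias `1 + gcBiasCoeff * (gc - 0.45)` and by
#' mappability.  A tenth of windows receive reduced mappability so the
#' mappability filter and division are exercised.
#'
#' @param w True fraction of cells with a Y chromosome, in \[0, 1.1\].
#' @param depth Sequencing depth (default 30).
#' @param windowSize Window width in bp (default 10000).
#' @param readLength Read length in bp (default 150).
#' @param gcBiasCoeff Strength of the linear GC bias (default 0 = none).
#' @param nAutosomalWindows,nYWindows Window counts (defaults 4000 / 400).
#' @param seed Optional integer seed.
#' @param region MSY interval for Y window placement.
#' @return A window `data.frame` (`chrom`, `start`, `end`, `count`, `gc`,
#'   `mappability`) with the truth in attribute `trueFractionWithY`.
#' @export
simulateWgsWindows <- function(w, depth = 30, windowSize = 10000L,
                               readLength = 150L, gcBiasCoeff = 0,
                               nAutosomalWindows = 4000L, nYWindows = 400L,
                               seed = NULL, region = msyRegion()) {
    stopifnot(depth > 0, w >= 0, w <= 1.1)
    .setSeed(seed)
    lambda1 <- depth * windowSize / readLength / 2
    n <- nAutosomalWindows + nYWindows
    gc <- stats::runif(n, 0.3, 0.6)
    map <- ifelse(stats::runif(n) < 0.9, 1, stats::runif(n, 0.4, 0.95))
    copies <- c(rep(2, nAutosomalWindows), rep(w, nYWindows))
    bias <- 1 + gcBiasCoeff * (gc - 0.45)
    counts <- stats::rpois(n, copies * lambda1 * pmax(bias, 0) * map)
    autoChrom <- rep(as.character(1:22),
        length.out = nAutosomalWindows)
    starts <- c(
        as.integer(seq_len(nAutosomalWindows) %/% 22 + 1) * windowSize,
        start(region)[1] - 1L + (seq_len(nYWindows) - 1L) * windowSize)
    out <- data.frame(chrom = c(autoChrom, rep("Y", nYWindows)),
        start = starts, end = starts + windowSize,
        count = counts, gc = gc, mappability = map,
        stringsAsFactors = FALSE)
    attr(out, "trueFractionWithY") <- w
    out
}

#' Simulate one ddPCR well at a known LOY fraction
#'
#' Binomial droplet positivity under Poisson partitioning: each of `n`
#' droplets is AMELX (VIC) positive with probability `1 - exp(-lambdaX)`
#' and AMELY (FAM) positive with probability `1 - exp(-w * lambdaX)`.
#' Channels are generated independently (double-positive droplets are not
#' modelled separately).
#'
#' @param w True fraction of cells with a Y chromosome (>= 0).
#' @param lambdaX Mean AMELX copies per droplet (default 0.2).
#' @param droplets Droplets per well (default 15000).
#' @param seed Optional integer seed.
#' @param sampleId,wellId Identifiers for the output row.
#' @return A one-row well `data.frame` with the truth in attribute
#'   `trueFractionWithY`.
#' @examples
#' simulateDdpcrWell(0.7, seed = 1)
#' @export
simulateDdpcrWell <- function(w, lambdaX = 0.2, droplets = 15000L,
                              seed = NULL, sampleId = "sim1",
                              wellId = "A01") {
    stopifnot(lambdaX > 0, w >= 0)
    .setSeed(seed)
    out <- data.frame(sample_id = sampleId, well_id = wellId,
        droplets_total = as.integer(droplets),
        fam_positive = stats::rbinom(1, droplets, 1 - exp(-w * lambdaX)),
        vic_positive = stats::rbinom(1, droplets, 1 - exp(-lambdaX)),
        stringsAsFactors = FALSE)
    attr(out, "trueFractionWithY") <- w
    out
}

#' Simulate a complete longitudinal cohort across all three pathways
#'
#' Generates a ground-truth-labelled cohort mirroring a longitudinal study
#' of aging men: by default 276 subjects contributing 798 blood draws at
#' ages 70-93, each subject sampled 2-5 times over at most 22.2 years,
#' with archetype-labelled LOY trajectories (about one third progressors),
#' per-wave array batches with technical offsets, and — for a subset
#' matching the pairwise study design — duplicate ddPCR wells (121 samples)
#' and windowed sequencing counts (26 of those).  The random draw-count
#' schedule is repaired deterministically so the default configuration
#' reproduces the cohort scale exactly.
#'
#' @param nSubjects,nSamples Cohort size (defaults 276 subjects, 798
#'   samples).
#' @param ageRange Sampling age range in years (default 70-93).
#' @param drawsRange Draws per subject (default 2-5).
#' @param maxSpan Maximum follow-up span per subject in years
#'   (default 22.2).
#' @param archetypeMix Named proportions over the four archetypes (must
#'   sum to 1); subjects with fewer than 3 draws never receive `complex`.
#' @param goyFraction Fraction of stable subjects simulated with mosaic
#'   gain of Y (baseline fraction-with-Y above 1; default 0.02).
#' @param nMsyProbes,nAutosomalProbes,probeNoiseSd Array generator
#'   settings.
#' @param batchOffsets Named numeric vector of per-wave MSY offsets; wave
#'   labels follow the draw index.
#' @param ddpcrN,wgsN Sizes of the pairwise-technology subsets (defaults
#'   121 and 26).
#' @param dropletsPerWell,lambdaX ddPCR generator settings.
#' @param depth,windowSize,nAutosomalWindows,nYWindows Sequencing
#'   generator settings.
#' @param seed Master seed; the seed fully determines every output.
#' @return A list of class `"loyCohort"`: `lrr` ([ArrayLRRSet-class] of all
#'   samples), `metadata` (`sampleId`, `subjectId`, `batchId`, `age`,
#'   `arrayVersion`), `truth` (per-sample true fraction-with-Y and
#'   archetype), `ddpcrWells`, `wgsWindows` (long table with `sample_id`),
#'   and `params`.
#' @seealso [writeCohort()] to emit the on-disk dialects every reader
#'   accepts.
#' @export
simulateCohort <- function(nSubjects = 276L, nSamples = 798L,
                           ageRange = c(70, 93), drawsRange = c(2L, 5L),
                           maxSpan = 22.2,
                           archetypeMix = c(progressor = 0.34,
                               stable = 0.50, decliner = 0.06,
                               complex = 0.10),
                           goyFraction = 0.02,
                           nMsyProbes = 1200L, nAutosomalProbes = 2000L,
                           probeNoiseSd = 0.15,
                           batchOffsets = c(wave1 = 0, wave2 = -0.05,
                               wave3 = 0.03, wave4 = -0.02, wave5 = 0.04),
                           ddpcrN = 121L, wgsN = 26L,
                           dropletsPerWell = 15000L, lambdaX = 0.2,
                           depth = 30, windowSize = 10000L,
                           nAutosomalWindows = 2000L, nYWindows = 200L,
                           seed = 1L) {
    stopifnot(abs(sum(archetypeMix) - 1) < 1e-8,
        all(names(archetypeMix) %in%
            c("progressor", "stable", "decliner", "complex")))
    minGap <- 2.5
    if (maxSpan < minGap * (drawsRange[2] - 1))
        stop("infeasible schedule: maxSpan too short for the requested draws")
    if (nSamples < nSubjects * drawsRange[1] ||
        nSamples > nSubjects * drawsRange[2])
        stop("infeasible schedule: nSamples outside the draws-per-subject range")
    .setSeed(seed)

    ## draw counts, repaired to the exact sample total
    k <- sample(seq(drawsRange[1], drawsRange[2]), nSubjects,
        replace = TRUE, prob = c(0.45, 0.30, 0.14, 0.11)[
            seq_len(drawsRange[2] - drawsRange[1] + 1)])
    while (sum(k) != nSamples) {
        if (sum(k) > nSamples) {
            cand <- which(k > drawsRange[1])
            i <- cand[sample.int(length(cand), 1)]
            k[i] <- k[i] - 1L
        } else {
            cand <- which(k < drawsRange[2])
            i <- cand[sample.int(length(cand), 1)]
            k[i] <- k[i] + 1L
        }
    }

    subjects <- sprintf("subj%03d", seq_len(nSubjects))
    meta <- truth <- vector("list", nSubjects)
    wTrue <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
        ki <- k[i]
        if (ki > 1L) {
            maxGap <- min(8, maxSpan / (ki - 1))
            gaps <- stats::runif(ki - 1, minGap, maxGap)
            a0 <- stats::runif(1, ageRange[1], ageRange[2] - sum(gaps))
            ages <- round(a0 + cumsum(c(0, gaps)), 1)
        } else {
            ages <- round(stats::runif(1, ageRange[1], ageRange[2]), 1)
        }
        mix <- archetypeMix
        if (ki < 3L) {
            mix["complex"] <- 0
            mix <- mix / sum(mix)
        }
        arch <- sample(names(mix), 1, prob = mix)
        baseW <- NULL
        if (arch == "stable" && stats::runif(1) < goyFraction)
            baseW <- stats::runif(1, 1.02, 1.08)
        w <- simulateTrajectory(arch, ages, baseW = baseW)
        sid <- sprintf("%s_d%d", subjects[i], seq_len(ki))
        batch <- paste0("wave", seq_len(ki))
        meta[[i]] <- data.frame(sampleId = sid, subjectId = subjects[i],
            batchId = batch, age = ages,
            arrayVersion = paste0("v", ((seq_len(ki) - 1L) %% 3L) + 1L),
            stringsAsFactors = FALSE)
        truth[[i]] <- data.frame(subjectId = subjects[i], sampleId = sid,
            age = ages, trueFractionWithY = w, archetype = arch,
            batchId = batch, stringsAsFactors = FALSE)
        wTrue[[i]] <- w
    }
    meta <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)
    w <- unlist(wTrue, use.names = FALSE)
    offsets <- batchOffsets[meta$batchId]
    offsets[is.na(offsets)] <- 0

    ## common manifest + LRR matrix, MSY probes carry signal and offset
    region <- msyRegion()
    width <- end(region)[1] - start(region)[1] + 1L
    msyPos <- sort(sample.int(width, nMsyProbes)) + start(region)[1] - 1L
    autoChrom <- sort(rep(as.character(1:22),
        length.out = nAutosomalProbes))
    autoPos <- sample.int(2.4e8, nAutosomalProbes, replace = TRUE)
    gr <- GRanges(c(autoChrom, rep("Y", nMsyProbes)),
        IRanges(c(autoPos, msyPos), width = 1),
        probeId = c(sprintf("auto_%05d", seq_len(nAutosomalProbes)),
            sprintf("msy_%05d", seq_len(nMsyProbes))))
    m <- nrow(meta)
    autoLrr <- matrix(stats::rnorm(nAutosomalProbes * m, 0, probeNoiseSd),
        nrow = nAutosomalProbes)
    msyMu <- 0.5 * log2(w) + offsets
    msyLrr <- matrix(stats::rnorm(nMsyProbes * m,
        mean = rep(msyMu, each = nMsyProbes), sd = probeNoiseSd),
        nrow = nMsyProbes)
    lrr <- rbind(autoLrr, msyLrr)
    colnames(lrr) <- meta$sampleId
    arr <- ArrayLRRSet(lrr, gr, meta)

    ## pairwise-technology subsets: oldest draw of ddpcrN random subjects
    lastIdx <- vapply(split(seq_len(m), meta$subjectId),
        function(ii) ii[which.max(meta$age[ii])], integer(1))
    ddpcrIdx <- sort(sample(lastIdx, min(ddpcrN, length(lastIdx))))
    wells <- do.call(rbind, lapply(ddpcrIdx, function(j) {
        pv <- 1 - exp(-lambdaX)
        pf <- 1 - exp(-w[j] * lambdaX)
        data.frame(sample_id = rep(meta$sampleId[j], 2),
            well_id = c("A01", "A02"),
            droplets_total = as.integer(dropletsPerWell),
            fam_positive = stats::rbinom(2, dropletsPerWell, pf),
            vic_positive = stats::rbinom(2, dropletsPerWell, pv),
            stringsAsFactors = FALSE)
    }))
    wgsIdx <- sort(sample(ddpcrIdx, min(wgsN, length(ddpcrIdx))))
    wgs <- do.call(rbind, lapply(wgsIdx, function(j) {
        win <- simulateWgsWindows(min(w[j], 1.1), depth = depth,
            windowSize = windowSize, gcBiasCoeff = 0.3,
            nAutosomalWindows = nAutosomalWindows, nYWindows = nYWindows)
        cbind(sample_id = meta$sampleId[j], win,
            stringsAsFactors = FALSE)
    }))

    structure(list(lrr = arr, metadata = meta, truth = truth,
        ddpcrWells = wells, wgsWindows = wgs,
        params = list(seed = seed, nSubjects = nSubjects,
            nSamples = nSamples, archetypeMix = archetypeMix,
            probeNoiseSd = probeNoiseSd, batchOffsets = batchOffsets)),
        class = "loyCohort")
}

#' @export
print.loyCohort <- function(x, ...) {
    cat(sprintf("Synthetic LOY cohort: %d subjects, %d samples (seed %d)\n",
        length(unique(x$metadata$subjectId)), nrow(x$metadata),
        x$params$seed))
    cat(sprintf("  archetypes: %s\n", paste(sprintf("%s=%d",
        names(table(x$truth$archetype[!duplicated(x$truth$subjectId)])),
        table(x$truth$archetype[!duplicated(x$truth$subjectId)])),
        collapse = ", ")))
    cat(sprintf("  ddPCR wells: %d | sequencing windows: %d\n",
        nrow(x$ddpcrWells), nrow(x$wgsWindows)))
    invisible(x)
}

#' Write a simulated cohort to disk in the formats the readers accept
#'
#' Emits `report.tsv` + `manifest.csv` (long array dialect, see
#' [readLRRReport()]), `windows.tsv` (with a `sample_id` column),
#' `wells.csv`, `metadata.tsv` and `truth.tsv`.  Output is deterministic:
#' the same cohort writes byte-identical files.
#'
#' @param cohort A `"loyCohort"` from [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(inherits(cohort, "loyCohort"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(report = file.path(dir, "report.tsv"),
        manifest = file.path(dir, "manifest.csv"),
        windows = file.path(dir, "windows.tsv"),
        wells = file.path(dir, "wells.csv"),
        metadata = file.path(dir, "metadata.tsv"),
        truth = file.path(dir, "truth.tsv"))
    writeLRRReport(cohort$lrr, paths["report"], paths["manifest"])
    utils::write.table(cohort$wgsWindows, paths["windows"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.csv(cohort$ddpcrWells, paths["wells"], row.names = FALSE,
        quote = FALSE)
    utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth, paths["truth"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(paths)
}
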