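# in-code fixtures: tiny report/manifest pairs written to tempfiles

writeTinyManifest <- function(path = tempfile(fileext = ".csv")) {
    man <- data.frame(
        `SNP Name` = c("pY1", "pY2", "pY3", "pA1", "pA2"),
        Chr = c("Y", "Y", "Y", "1", "2"),
        Position = c(2781480L, 2781479L, 30000000L, 1000L, 2000L),
        check.names = FALSE)
    write.csv(man, path, row.names = FALSE, quote = FALSE)
    path
}

writeTinyReport <- function(path = tempfile(fileext = ".tsv"),
                            samples = c("s1", "s2"),
                            probes = c("pY1", "pY2", "pY3", "pA1", "pA2"),
                            lrr = NULL) {
    if (is.null(lrr))
        lrr <- round(seq(-0.4, 0.4, length.out = length(samples) *
            length(probes)), 3)
    rep <- data.frame(
        `Sample ID` = rep(samples, each = length(probes)),
        `SNP Name` = rep(probes, times = length(samples)),
        `Log R Ratio` = lrr,
        check.names = FALSE)
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# lean array-pathway replicate: MSY probe draws -> median -> LOY%
# (the numeric computeMLRRY method is the same estimator the full
# ArrayLRRSet pathway dispatches to)
simulateMsyLoyEstimate <- function(w, nProbes = 2000, sd = 0.15) {
    m <- computeMLRRY(rnorm(nProbes, 0.5 * log2(w), sd))
    loyPercentFromMLRRY(m)
}
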