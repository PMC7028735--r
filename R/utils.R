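# shared internal helpers

.CANONICAL_CHROMS <- c(as.character(1:22), "X", "Y")

# "chrY"/"chry"/"24" are normalised to "Y"; unknown labels pass through
# unchanged so callers can decide whether to drop them.
.normalizeChrom <- function(chrom) {
    chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
    chrom[chrom == "23"] <- "X"
    chrom[chrom == "24"] <- "Y"
    toupper(chrom) -> up
    ifelse(up %in% c("X", "Y"), up, chrom)
}

# round-half-away-from-zero, the convention used for the published
# calibration constants (0.9242 -> 1, 1.7703 -> 2)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.assertFinite <- function(x, what) {
    if (!is.numeric(x) || any(!is.finite(x)))
        stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
    invisible(x)
}

.setSeed <- function(seed) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L)
            stop("'seed' must be a single integer")
        set.seed(as.integer(seed))
    }
    invisible(NULL)
}

# deterministic stream of sub-seeds below 2^31, derived from a master seed
.subSeeds <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, n)
}
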