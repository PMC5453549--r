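# Internal helpers shared across modules.

# Derive a stage/line-specific seed from the master seed so that every
# sampling stage uses its own stream, with no global-state coupling.
# Kept below 2^31 - 1.
deriveSeed <- function(seed, stage, line = "") {
    h <- sum(utf8ToInt(paste0(stage, ":", line)) *
                 seq_along(utf8ToInt(paste0(stage, ":", line)))) %% 99991L
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Centered moving average of width w, truncated at the ends (the window is
# intersected with the vector; no padding). For even w the window extends
# floor((w-1)/2) left and floor(w/2) right of the focal element.
movingAverage <- function(x, w) {
    if (w <= 1L) return(x)
    n <- length(x)
    hl <- (w - 1L) %/% 2L
    hr <- w %/% 2L
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(i - hl, 1L)
    hi <- pmin(i + hr, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# All 4^k k-mers in lexicographic (A<C<G<T) order; matches the column order
# of Biostrings::oligonucleotideFrequency.
allKmers <- function(k) {
    bases <- c("A", "C", "G", "T")
    m <- do.call(expand.grid,
                 c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE))
    # expand.grid varies the first factor fastest; reverse for lexicographic
    do.call(paste0, rev(m))
}

# Encode each overlapping k-mer start position of a chromosome sequence as
# an index in 1..4^k (lexicographic), NA where the window has a non-ACGT
# base. Returns integer vector of length len - k + 1 (empty if len < k).
kmerIndexVector <- function(seqchar, k) {
    n <- nchar(seqchar)
    if (n < k) return(integer(0))
    b <- utf8ToInt(seqchar)
    code <- integer(n)
    code[] <- NA_integer_
    code[b == 65L] <- 0L  # A
    code[b == 67L] <- 1L  # C
    code[b == 71L] <- 2L  # G
    code[b == 84L] <- 3L  # T
    np <- n - k + 1L
    idx <- numeric(np)
    for (j in seq_len(k)) {
        idx <- idx + as.numeric(code[j:(j + np - 1L)]) * 4^(k - j)
    }
    as.integer(idx + 1)
}

# Indicator of bases lying inside a poly(dA:dT) homopolymer run (all-A or
# all-T) of length >= minRun.
polyARunMask <- function(seqchar, minRun = 5L) {
    b <- utf8ToInt(seqchar)
    isA <- b == 65L
    isT <- b == 84L
    mask <- logical(length(b))
    for (v in list(isA, isT)) {
        r <- rle(v)
        keep <- r$values & r$lengths >= minRun
        if (any(keep)) {
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (i in which(keep)) mask[starts[i]:ends[i]] <- TRUE
        }
    }
    mask
}

# Indicator over dinucleotide start positions (length n-1): TRUE where the
# dinucleotide starting there is in {AA, AT, TA, TT} (W = A/T at both bases).
wwMask <- function(seqchar) {
    b <- utf8ToInt(seqchar)
    isW <- b == 65L | b == 84L
    n <- length(b)
    if (n < 2L) return(logical(0))
    isW[-n] & isW[-1L]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
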