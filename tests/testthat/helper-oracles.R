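# Independent brute-force oracles. These are deliberately naive
# (character-level nested loops) and share no code with the package
# implementations they check.

oracleBases <- function(genome, chrom) {
    strsplit(as.character(genome[[chrom]]), "")[[1]]
}

# phasogram by explicit per-midpoint, per-offset dinucleotide lookup
oraclePhasogram <- function(track, genome, flank = 73L) {
    offsets <- (-flank):flank
    ww <- c("AA", "AT", "TA", "TT")
    ss <- c("CC", "CG", "GC", "GG")
    wwN <- ssN <- numeric(length(offsets))
    used <- 0
    for (cn in names(midpointCounts(track))) {
        b <- oracleBases(genome, cn)
        x <- midpointCounts(track)[[cn]]
        for (m in which(x > 0)) {
            if (m - flank < 1 || m + flank + 1 > length(b)) next
            win <- b[(m - flank):(m + flank + 1)]
            if (any(!win %in% c("A", "C", "G", "T"))) next
            w <- x[m]
            used <- used + w
            for (i in seq_along(offsets)) {
                d <- paste0(b[m + offsets[i]], b[m + offsets[i] + 1])
                if (d %in% ww) wwN[i] <- wwN[i] + w
                if (d %in% ss) ssN[i] <- ssN[i] + w
            }
        }
    }
    list(offsets = offsets, ww_freq = wwN / used, ss_freq = ssN / used,
         n_midpoints_used = used)
}

# overlapping k-mer counts by substring extraction
oracleKmerCounts <- function(genome, k) {
    counts <- integer(0)
    for (cn in names(genome)) {
        s <- as.character(genome[[cn]])
        n <- nchar(s)
        if (n < k) next
        for (i in 1:(n - k + 1)) {
            w <- substr(s, i, i + k - 1)
            if (grepl("[^ACGT]", w)) next
            counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
        }
    }
    counts
}

oracleKmerGenomeFrequency <- function(genome, k) {
    counts <- oracleKmerCounts(genome, k)
    full <- stats::setNames(numeric(4^k), NucleoScope:::allKmers(k))
    full[names(counts)] <- counts
    full / sum(full)
}

# weighted window k-mer counting around midpoints
oracleKmerNucleosomeFrequency <- function(track, genome, k, flank = 73L) {
    full <- stats::setNames(numeric(4^k), NucleoScope:::allKmers(k))
    for (cn in names(midpointCounts(track))) {
        s <- as.character(genome[[cn]])
        x <- midpointCounts(track)[[cn]]
        for (m in which(x > 0)) {
            if (m - flank < 1 || m + flank > nchar(s)) next
            win <- substr(s, m - flank, m + flank)
            if (grepl("[^ACGT]", win)) next
            for (i in 1:(nchar(win) - k + 1)) {
                w <- substr(win, i, i + k - 1)
                full[w] <- full[w] + x[m]
            }
        }
    }
    full / sum(full)
}

# per-position membership count
oracleCoverage <- function(gr, seqlen, chrom) {
    depth <- integer(seqlen)
    sel <- as.character(GenomicRanges::seqnames(gr)) == chrom
    st <- GenomicRanges::start(gr)[sel]
    en <- GenomicRanges::end(gr)[sel]
    for (pos in seq_len(seqlen))
        depth[pos] <- sum(st <= pos & en >= pos)
    depth
}

# occurrence-centred window rates by direct scan
oracleHeptamerRates <- function(gr, genome, k = 7L, regionWidth = 200L) {
    kmers <- NucleoScope:::allKmers(k)
    sums <- stats::setNames(numeric(4^k), kmers)
    nuse <- stats::setNames(numeric(4^k), kmers)
    half <- regionWidth %/% 2L
    coff <- (k - 1L) %/% 2L
    for (cn in names(genome)) {
        s <- as.character(genome[[cn]])
        L <- nchar(s)
        sel <- as.character(GenomicRanges::seqnames(gr)) == cn
        st <- GenomicRanges::start(gr)[sel]
        en <- GenomicRanges::end(gr)[sel]
        for (p in 1:(L - k + 1)) {
            w <- substr(s, p, p + k - 1)
            if (grepl("[^ACGT]", w)) next
            ctr <- p + coff
            lo <- ctr - half
            hi <- ctr + regionWidth - half - 1L
            if (lo < 1 || hi > L) next
            d <- 0
            for (pos in lo:hi) d <- d + sum(st <= pos & en >= pos)
            sums[w] <- sums[w] + d / regionWidth
            nuse[w] <- nuse[w] + 1
        }
    }
    rates <- ifelse(nuse > 0, (sums / nuse) * 1e6 / length(gr), NA_real_)
    stats::setNames(rates, kmers)
}

# Benjamini-Hochberg by direct sort
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    q[o] <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
    q
}
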