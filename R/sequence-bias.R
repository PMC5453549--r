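# Dinucleotide periodicity around dyads and k-mer genome-vs-nucleosome
# depletion statistics.

# per-chromosome helpers ----------------------------------------------------

# cumulative count of non-ACGT bases, for O(1) window ambiguity tests
ambiguityCumsum <- function(seqchar) {
    b <- utf8ToInt(seqchar)
    bad <- !(b == 65L | b == 67L | b == 71L | b == 84L)
    cumsum(c(0L, bad))
}

# dinucleotide class per start position: 1 = WW {AA,AT,TA,TT},
# 2 = SS {CC,CG,GC,GG}, 0 = mixed, NA = contains non-ACGT
dinucClassVector <- function(seqchar) {
    b <- utf8ToInt(seqchar)
    n <- length(b)
    if (n < 2L) return(integer(0))
    w <- b == 65L | b == 84L
    s <- b == 67L | b == 71L
    ok <- w | s
    cls <- integer(n - 1L)
    cls[w[-n] & w[-1L]] <- 1L
    cls[s[-n] & s[-1L]] <- 2L
    cls[!(ok[-n] & ok[-1L])] <- NA_integer_
    cls
}

#' Dinucleotide frequency by distance from the nucleosome dyad
#'
#' For every offset in \code{-flank..+flank} from each fragment midpoint,
#' tallies the forward-strand dinucleotide starting at that position into
#' the A/T class (AA, AT, TA, TT) and the C/G class (CC, CG, GC, GG),
#' weighted by the midpoint multiplicity. Midpoints whose window (through
#' offset \code{+flank}, i.e. bases \code{midpoint - flank} to
#' \code{midpoint + flank + 1}) extends outside the chromosome or contains
#' an ambiguous base are skipped and counted.
#'
#' @param track a [MidpointTrack-class].
#' @param genome a [Biostrings::DNAStringSet-class] covering the track.
#' @param flank maximum offset from the dyad (default 73, the 147-bp
#'   nucleosome footprint).
#' @return object of class \code{"Phasogram"}: list with \code{offsets},
#'   \code{ww_freq}, \code{ss_freq}, \code{n_midpoints_used},
#'   \code{n_skipped}.
#' @export
computePhasogram <- function(track, genome, flank = 73L) {
    offsets <- (-flank):flank
    wwNum <- numeric(length(offsets))
    ssNum <- numeric(length(offsets))
    used <- 0
    skipped <- 0
    for (cn in names(track@counts)) {
        if (!cn %in% names(genome))
            stopf("chromosome '%s' missing from genome", cn)
        x <- track@counts[[cn]]
        pos <- which(x > 0L)
        if (!length(pos)) next
        w <- x[pos]
        seqchar <- as.character(genome[[cn]])
        L <- nchar(seqchar)
        inb <- pos - flank >= 1L & pos + flank + 1L <= L
        amb <- ambiguityCumsum(seqchar)
        clean <- inb
        clean[inb] <- (amb[pos[inb] + flank + 2L] -
                           amb[pos[inb] - flank]) == 0L
        skipped <- skipped + sum(w[!clean])
        pos <- pos[clean]
        w <- w[clean]
        if (!length(pos)) next
        used <- used + sum(w)
        cls <- dinucClassVector(seqchar)
        for (i in seq_along(offsets)) {
            cj <- cls[pos + offsets[i]]
            wwNum[i] <- wwNum[i] + sum(w[cj == 1L])
            ssNum[i] <- ssNum[i] + sum(w[cj == 2L])
        }
    }
    if (used == 0)
        stopf("no usable midpoints (all outside chromosome bounds or in ambiguous sequence)")
    structure(list(offsets = offsets, ww_freq = wwNum / used,
                   ss_freq = ssNum / used, n_midpoints_used = used,
                   n_skipped = skipped),
              class = c("Phasogram", "list"))
}

#' Genomic k-mer frequencies
#'
#' Overlapping forward-strand k-mer counts over all chromosomes (windows
#' containing ambiguous bases contribute nothing), normalized to sum to 1
#' over all 4^k words in lexicographic order.
#'
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param k word length (>= 1).
#' @return named numeric vector of length 4^k summing to 1.
#' @export
kmerGenomeFrequency <- function(genome, k) {
    k <- as.integer(k)
    if (k < 1L) stopf("k must be >= 1")
    if (all(width(genome) < k))
        stopf("genome sequences are all shorter than k = %d", k)
    counts <- colSums(Biostrings::oligonucleotideFrequency(genome, width = k))
    tot <- sum(counts)
    if (tot == 0) stopf("no unambiguous %d-mers in genome", k)
    counts / tot
}

#' Nucleosomal k-mer frequencies
#'
#' Counts k-mers within the 147-bp window centred on each midpoint
#' (midpoint +/- 73), each window weighted by its midpoint count; windows
#' extending outside the chromosome or containing ambiguous bases are
#' skipped entirely. Normalized to sum to 1.
#'
#' @param track a [MidpointTrack-class].
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param k word length.
#' @param flank half-window (default 73).
#' @return named numeric vector of length 4^k summing to 1.
#' @export
kmerNucleosomeFrequency <- function(track, genome, k, flank = 73L) {
    k <- as.integer(k)
    if (k < 1L) stopf("k must be >= 1")
    nk <- 4L^k
    tally <- numeric(nk)
    used <- 0
    for (cn in names(track@counts)) {
        if (!cn %in% names(genome))
            stopf("chromosome '%s' missing from genome", cn)
        x <- track@counts[[cn]]
        if (!any(x > 0L)) next
        seqchar <- as.character(genome[[cn]])
        L <- nchar(seqchar)
        pos <- which(x > 0L)
        w <- x[pos]
        inb <- pos - flank >= 1L & pos + flank <= L
        amb <- ambiguityCumsum(seqchar)
        clean <- inb
        clean[inb] <- (amb[pos[inb] + flank + 1L] -
                           amb[pos[inb] - flank]) == 0L
        pos <- pos[clean]
        w <- w[clean]
        if (!length(pos)) next
        used <- used + sum(w)
        # weight of each k-mer start position p = total midpoint weight of
        # windows covering p fully: midpoints in [p + k - 1 - flank, p + flank]
        wvec <- numeric(L)
        wvec[pos] <- w
        cw <- cumsum(c(0, wvec))
        npos <- L - k + 1L
        p <- seq_len(npos)
        lo <- pmax(p + k - 1L - flank, 1L)
        hi <- pmin(p + flank, L)
        W <- cw[hi + 1L] - cw[lo]
        nz <- which(W > 0)
        if (!length(nz)) next
        idx <- kmerIndexVector(seqchar, k)[nz]
        agg <- rowsum(W[nz], idx)
        tally[as.integer(rownames(agg))] <-
            tally[as.integer(rownames(agg))] + agg[, 1L]
    }
    if (used == 0)
        stopf("no usable midpoints for nucleosomal k-mer counting")
    names(tally) <- allKmers(k)
    tally / sum(tally)
}

#' Log2 genome-over-nucleosome depletion statistic
#'
#' \code{log2(P / P_nucleosome)} per k-mer. Positive values mean the k-mer
#' is depleted from nucleosomal DNA relative to its genomic frequency;
#' negative values mean it is preferentially found within nucleosomal DNA.
#' K-mers with either frequency equal to zero are returned as \code{NA}
#' (undefined) and should be excluded from distribution summaries.
#'
#' @param P genomic frequency vector from [kmerGenomeFrequency()].
#' @param Pnucleosome nucleosomal frequency vector from
#'   [kmerNucleosomeFrequency()], aligned on the same k-mers.
#' @return named numeric vector of per-k-mer log2 ratios.
#' @export
log2Depletion <- function(P, Pnucleosome) {
    if (length(P) != length(Pnucleosome))
        stopf("frequency vectors differ in length (%d vs %d)",
              length(P), length(Pnucleosome))
    if (!is.null(names(P)) && !is.null(names(Pnucleosome)) &&
        !identical(names(P), names(Pnucleosome)))
        stopf("frequency vectors are not aligned on the same k-mers")
    out <- ifelse(P > 0 & Pnucleosome > 0, log2(P / Pnucleosome), NA_real_)
    names(out) <- names(P)
    out
}

#' Full k-mer enrichment analysis for one dataset
#'
#' Convenience wrapper assembling genomic frequencies, nucleosomal
#' frequencies, and the log2 depletion statistic.
#'
#' @param track a [MidpointTrack-class].
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param k word length (default 5, the pentamer analysis).
#' @return list with \code{k}, \code{P}, \code{P_nucleosome},
#'   \code{log2_ratio}.
#' @export
kmerEnrichment <- function(track, genome, k = 5L) {
    P <- kmerGenomeFrequency(genome, k)
    Pn <- kmerNucleosomeFrequency(track, genome, k)
    list(k = as.integer(k), P = P, P_nucleosome = Pn,
         log2_ratio = log2Depletion(P, Pn))
}

#' Pentamer class distributions of the depletion statistic
#'
#' Partitions the 1,024 pentamers into the 32 containing only A and T, the
#' 32 containing only G and C, and the complete set, and summarizes the
#' log2 depletion statistic within each class.
#'
#' @param enrichment result of [kmerEnrichment()] with \code{k = 5}.
#' @return named list of three elements (\code{at_only}, \code{gc_only},
#'   \code{all}), each a list with \code{kmers}, \code{values} (NA-free),
#'   and \code{quantiles}.
#' @export
pentamerClassDistributions <- function(enrichment) {
    if (enrichment$k != 5L)
        stopf("pentamer class definitions require k = 5 (got k = %d)",
              enrichment$k)
    kmers <- names(enrichment$log2_ratio)
    atOnly <- !grepl("[CG]", kmers)
    gcOnly <- !grepl("[AT]", kmers)
    mk <- function(sel) {
        v <- enrichment$log2_ratio[sel]
        vv <- v[!is.na(v)]
        list(kmers = kmers[sel], values = v,
             quantiles = stats::quantile(vv, c(0, .25, .5, .75, 1),
                                         names = TRUE))
    }
    list(at_only = mk(atOnly), gc_only = mk(gcOnly),
         all = mk(rep(TRUE, length(kmers))))
}

#' Dominant period of the phasogram A/T signal
#'
#' Estimates the dominant oscillation period of \code{ww_freq} over a
#' central offset range by locating the first local maximum of the
#' autocorrelation of the detrended signal.
#'
#' @param phasogram result of [computePhasogram()].
#' @param range offsets to use (default -60..60).
#' @param maxLag largest lag considered (default 20).
#' @return estimated period in bp.
#' @export
phasogramPeriod <- function(phasogram, range = c(-60L, 60L), maxLag = 20L) {
    sel <- phasogram$offsets >= range[1] & phasogram$offsets <= range[2]
    y <- phasogram$ww_freq[sel]
    y <- y - movingAverage(y, 11L)  # remove the slow footprint-scale trend
    ac <- stats::acf(y, lag.max = maxLag, plot = FALSE)$acf[-1]
    lags <- seq_len(maxLag)
    # strongest interior local maximum (lag >= 2 avoids trivial smoothness)
    locmax <- which(diff(sign(diff(c(-Inf, ac, -Inf)))) == -2)
    locmax <- locmax[locmax >= 2L & ac[locmax] > 0]
    if (!length(locmax)) return(NA_real_)
    locmax[which.max(ac[locmax])]
}
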