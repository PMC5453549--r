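# Expression quantification and TSS-centred aggregate midpoint profiles.

#' Compute FPKM from exon read counts
#'
#' \code{fpkm = count / (length / 1000) / (librarySize / 1e6)}. The log10
#' values use a pseudocount of half the smallest nonzero FPKM for
#' zero-expression transcripts, which leaves ranks unchanged while keeping
#' the expression strata well defined.
#'
#' @param exonCounts reads overlapping annotated exons, per transcript.
#' @param transcriptLengths transcript (exonic) lengths in bp, all > 0.
#' @param librarySize total mapped reads (> 0).
#' @param ids optional transcript identifiers.
#' @return data.frame with columns \code{transcript_id},
#'   \code{exon_read_count}, \code{transcript_length}, \code{fpkm},
#'   \code{log10_fpkm}.
#' @export
computeFpkm <- function(exonCounts, transcriptLengths, librarySize,
                        ids = NULL) {
    if (any(transcriptLengths <= 0))
        stopf("transcript lengths must be > 0")
    if (librarySize <= 0) stopf("librarySize must be > 0")
    if (length(exonCounts) != length(transcriptLengths))
        stopf("exonCounts and transcriptLengths differ in length")
    if (is.null(ids)) ids <- sprintf("t%04d", seq_along(exonCounts))
    fpkm <- exonCounts / (transcriptLengths / 1000) / (librarySize / 1e6)
    pseudo <- if (any(fpkm > 0)) min(fpkm[fpkm > 0]) / 2 else 1
    lf <- log10(ifelse(fpkm > 0, fpkm, pseudo))
    data.frame(transcript_id = ids, exon_read_count = exonCounts,
               transcript_length = transcriptLengths, fpkm = fpkm,
               log10_fpkm = lf, stringsAsFactors = FALSE)
}

#' Partition transcripts into expression strata
#'
#' Ranks transcripts on \code{log10_fpkm} (stable order for ties) and
#' assigns the bottom quartile to \code{low}, the top quartile to
#' \code{high}, and the middle half to \code{medium}. Stratum sizes differ
#' by at most one from the exact 25/50/25 split.
#'
#' @param table data.frame from [computeFpkm()] (needs
#'   \code{transcript_id} and \code{log10_fpkm}).
#' @return named list of three character vectors of transcript ids:
#'   \code{low}, \code{medium}, \code{high}.
#' @export
stratifyByExpression <- function(table) {
    n <- nrow(table)
    if (n < 4L) stopf("need at least 4 transcripts to stratify (got %d)", n)
    ord <- order(table$log10_fpkm)  # stable sort: ties keep input order
    nLow <- round(n * 0.25)
    nHigh <- round(n * 0.25)
    ids <- table$transcript_id[ord]
    list(low = ids[seq_len(nLow)],
         medium = ids[seq.int(nLow + 1L, n - nHigh)],
         high = ids[seq.int(n - nHigh + 1L, n)])
}

#' Aggregate midpoint profile around transcription start sites
#'
#' Sums midpoint counts at every strand-oriented offset in
#' \code{-flank..+flank} across the given TSSs (minus-strand genes are
#' mirrored so that negative offsets are always upstream), divides by the
#' number of TSSs used, and applies a centred moving average of width
#' \code{smooth} truncated at the ends. Duplicate TSS coordinates are
#' collapsed to one; TSSs whose window extends outside the chromosome are
#' dropped and counted.
#'
#' @param track a [MidpointTrack-class].
#' @param tss data.frame with columns \code{chrom}, \code{tss} (1-based),
#'   \code{strand} ("+" or "-").
#' @param flank half-window in bp (default 1000).
#' @param smooth smoothing window in bp (default 20); use 0 or 1 for no
#'   smoothing.
#' @param label stratum label carried in the result.
#' @return object of class \code{"TssProfile"}: list with \code{offsets},
#'   \code{rate} (midpoints per TSS per bp, smoothed), \code{raw}
#'   (unsmoothed), \code{rate_per_million} (raw scaled by 1e6 /
#'   total fragments, smoothed), \code{n_tss}, \code{n_dropped},
#'   \code{smoothing_window}, \code{label}.
#' @export
aggregateTss <- function(track, tss, flank = 1000L, smooth = 20L,
                         label = "all") {
    if (!nrow(tss)) stopf("empty TSS list")
    key <- paste(tss$chrom, tss$tss)
    tss <- tss[!duplicated(key), , drop = FALSE]
    offsets <- (-flank):flank
    acc <- numeric(length(offsets))
    used <- 0L
    dropped <- 0L
    for (cn in unique(tss$chrom)) {
        if (!cn %in% names(track@counts))
            stopf("chromosome '%s' missing from track", cn)
        x <- track@counts[[cn]]
        L <- length(x)
        sub <- tss[tss$chrom == cn, , drop = FALSE]
        ok <- sub$tss - flank >= 1L & sub$tss + flank <= L
        dropped <- dropped + sum(!ok)
        sub <- sub[ok, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            win <- x[(sub$tss[i] - flank):(sub$tss[i] + flank)]
            if (sub$strand[i] == "-") win <- rev(win)
            acc <- acc + win
            used <- used + 1L
        }
    }
    if (used == 0L) stopf("no TSS with a full +/-%d bp window", flank)
    raw <- acc / used
    sm <- if (smooth > 1L) movingAverage(raw, smooth) else raw
    structure(list(offsets = offsets, rate = sm, raw = raw,
                   rate_per_million = sm * 1e6 / track@totalFragments,
                   n_tss = used, n_dropped = dropped,
                   smoothing_window = as.integer(smooth), label = label),
              class = c("TssProfile", "list"))
}

#' Expression-stratified TSS profiles
#'
#' Computes [aggregateTss()] separately for the low, medium and high
#' expression strata of [stratifyByExpression()].
#'
#' @param track a [MidpointTrack-class].
#' @param tss data.frame with \code{transcript_id}, \code{chrom},
#'   \code{tss}, \code{strand}.
#' @param expression data.frame from [computeFpkm()] matching
#'   \code{transcript_id}.
#' @param flank,smooth as in [aggregateTss()].
#' @return named list of \code{"TssProfile"} objects (low/medium/high).
#' @export
stratifiedTssProfiles <- function(track, tss, expression, flank = 1000L,
                                  smooth = 20L) {
    strata <- stratifyByExpression(expression)
    out <- lapply(names(strata), function(s) {
        sub <- tss[tss$transcript_id %in% strata[[s]], , drop = FALSE]
        aggregateTss(track, sub, flank = flank, smooth = smooth, label = s)
    })
    names(out) <- names(strata)
    out
}
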