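# Per-heptamer occupancy rates, pairwise best-fit residuals, top-N outlier
# selection, and heptamer-centred midpoint profiles.

#' Locate all k-mer occurrences in a genome
#'
#' Forward-strand literal overlapping matches of every 4^k k-mer;
#' positions containing ambiguous bases are skipped. Complementary words
#' are kept distinct.
#'
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param k word length (default 7).
#' @return object of class \code{"KmerOccurrences"}: list with \code{k},
#'   \code{kmers}, \code{counts} (named, length 4^k), and \code{index}
#'   (per-chromosome integer vector giving the k-mer index at every start
#'   position, NA where ambiguous).
#' @export
heptamerOccurrences <- function(genome, k = 7L) {
    k <- as.integer(k)
    kmers <- allKmers(k)
    index <- lapply(names(genome), function(cn)
        kmerIndexVector(as.character(genome[[cn]]), k))
    names(index) <- names(genome)
    counts <- integer(4L^k)
    for (idx in index) {
        t <- tabulate(idx, nbins = 4L^k)
        counts <- counts + t
    }
    names(counts) <- kmers
    structure(list(k = k, kmers = kmers, counts = counts, index = index),
              class = c("KmerOccurrences", "list"))
}

# 1-based start positions of one k-mer on one chromosome
occurrencePositions <- function(occurrences, heptamer, chrom) {
    code <- match(heptamer, occurrences$kmers)
    if (is.na(code)) stopf("'%s' is not a valid %d-mer", heptamer,
                           occurrences$k)
    which(occurrences$index[[chrom]] == code)
}

#' Per-base-pair fragment coverage depth
#'
#' \code{depth(pos)} = number of fragments whose interval contains
#' \code{pos}.
#'
#' @param gr filtered fragments.
#' @param seqlengths named chromosome lengths.
#' @return object of class \code{"CoverageTrack"}: list with \code{depth}
#'   (per-chromosome integer vectors), \code{seqlengths},
#'   \code{totalFragments}.
#' @export
coverageTrack <- function(gr, seqlengths) {
    seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    cov <- GenomicRanges::coverage(gr, width = as.list(seqlengths))
    depth <- lapply(names(seqlengths), function(cn)
        as.integer(cov[[cn]]))
    names(depth) <- names(seqlengths)
    structure(list(depth = depth, seqlengths = seqlengths,
                   totalFragments = as.numeric(length(gr))),
              class = c("CoverageTrack", "list"))
}

#' Per-k-mer occupancy rate table
#'
#' For every occurrence of each k-mer, takes the 200-bp region centred on
#' the word's central base (\code{start + floor((k-1)/2)}), computes the
#' mean fragment coverage depth within it (occurrences whose region would
#' be clipped by a chromosome end are dropped), averages over occurrences,
#' and normalizes per million fragments:
#' \code{rate = mean(mean window depth) * 1e6 / totalFragments}.
#'
#' @param coverage a \code{"CoverageTrack"} from [coverageTrack()].
#' @param occurrences a \code{"KmerOccurrences"} from
#'   [heptamerOccurrences()] built on the same genome.
#' @param totalFragments fragment count for normalization (default from
#'   the coverage track).
#' @param regionWidth width of the occurrence-centred region (default 200).
#' @param label dataset identifier.
#' @return a [KmerRateTable-class].
#' @export
heptamerRates <- function(coverage, occurrences,
                          totalFragments = coverage$totalFragments,
                          regionWidth = 200L, label = "dataset") {
    k <- occurrences$k
    nk <- 4L^k
    half <- regionWidth %/% 2L
    centerOff <- (k - 1L) %/% 2L
    sums <- numeric(nk)
    nuse <- numeric(nk)
    for (cn in names(occurrences$index)) {
        if (!cn %in% names(coverage$depth))
            stopf("chromosome '%s' missing from coverage", cn)
        idx <- occurrences$index[[cn]]
        if (!length(idx)) next
        depth <- coverage$depth[[cn]]
        L <- length(depth)
        p <- seq_along(idx)
        ctr <- p + centerOff
        lo <- ctr - half
        hi <- ctr + regionWidth - half - 1L
        ok <- lo >= 1L & hi <= L & !is.na(idx)
        if (!any(ok)) next
        cs <- cumsum(c(0, depth))
        wmean <- (cs[hi[ok] + 1L] - cs[lo[ok]]) / regionWidth
        agg <- rowsum(cbind(wmean, 1), idx[ok])
        ids <- as.integer(rownames(agg))
        sums[ids] <- sums[ids] + agg[, 1L]
        nuse[ids] <- nuse[ids] + agg[, 2L]
    }
    rates <- ifelse(nuse > 0, (sums / nuse) * 1e6 / totalFragments, NA_real_)
    names(rates) <- occurrences$kmers
    new("KmerRateTable", label = label, k = k,
        occurrences = stats::setNames(as.integer(occurrences$counts),
                                      occurrences$kmers),
        rates = rates, totalFragments = as.numeric(totalFragments))
}

#' Best-fit-line residuals between two rate tables
#'
#' Ordinary least squares of \code{rate_b} on \code{rate_a} over the
#' k-mers with defined rates in both tables;
#' \code{residual = rate_b - (intercept + slope * rate_a)}.
#'
#' @param ta,tb [KmerRateTable-class] objects over the same k-mers.
#' @return list with \code{slope}, \code{intercept}, \code{residuals}
#'   (named over shared k-mers), \code{label_a}, \code{label_b}.
#' @export
pairwiseResiduals <- function(ta, tb) {
    if (ta@k != tb@k) stopf("rate tables have different k")
    ra <- ta@rates
    rb <- tb@rates
    shared <- !is.na(ra) & !is.na(rb)
    if (sum(shared) < 3L) stopf("fewer than 3 shared k-mers with rates")
    x <- ra[shared]
    y <- rb[shared]
    fit <- stats::lm.fit(cbind(1, x), y)
    coefs <- fit$coefficients
    res <- y - (coefs[1] + coefs[2] * x)
    # snap numerical noise to exact zero so degenerate (identical-table)
    # comparisons resolve by the documented lexicographic tie rule
    res[abs(res) < 1e-9 * max(abs(y), 1)] <- 0
    list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
         residuals = stats::setNames(unname(res), names(x)),
         label_a = ta@label, label_b = tb@label)
}

#' Select residual outliers
#'
#' The \code{n} k-mers with the largest absolute residuals; ties at the
#' cutoff are broken by lexicographic k-mer order (deterministic).
#'
#' @param residuals named residual vector from [pairwiseResiduals()] (or
#'   the full fit object).
#' @param n number of outliers (default 20).
#' @return data.frame with \code{heptamer}, \code{residual}, \code{rank}.
#' @export
selectOutliers <- function(residuals, n = 20L) {
    if (is.list(residuals)) residuals <- residuals$residuals
    if (any(!is.finite(residuals))) stopf("residuals must be finite")
    ord <- order(-abs(residuals), names(residuals))
    take <- ord[seq_len(min(n, length(residuals)))]
    data.frame(heptamer = names(residuals)[take],
               residual = unname(residuals[take]),
               rank = seq_along(take), stringsAsFactors = FALSE)
}

#' Arithmetic mean-of-lines rate table
#'
#' Per-k-mer unweighted mean of the rates of several datasets (defined
#' only where every dataset has a defined rate).
#'
#' @param tables list of [KmerRateTable-class] objects.
#' @param label label for the combined table.
#' @return a [KmerRateTable-class].
#' @export
meanRateTable <- function(tables, label = "mean") {
    m <- vapply(tables, function(t) t@rates, numeric(length(tables[[1]]@rates)))
    rates <- rowMeans(m)
    new("KmerRateTable", label = label, k = tables[[1]]@k,
        occurrences = tables[[1]]@occurrences, rates = rates,
        totalFragments = mean(vapply(tables, function(t) t@totalFragments,
                                     numeric(1))))
}

#' Run every pairwise comparison of the heptamer screen
#'
#' Takes the per-line rate tables plus the in vitro table, forms the
#' mean-of-lines table, executes all unordered pairwise comparisons
#' (15 for four lines + mean + in vitro), selects the top-\code{topN}
#' outliers of each, and reports the union with per-comparison provenance
#' together with a residual matrix in the published layout (per-heptamer
#' residuals of each line versus the mean of lines, and of the mean
#' versus in vitro).
#'
#' @param lineTables named list of per-line [KmerRateTable-class] objects.
#' @param invitroTable [KmerRateTable-class] for reconstituted chromatin
#'   (optional; omit to compare lines and mean only).
#' @param topN outliers per comparison (default 20).
#' @return object of class \code{"OutlierReport"}: list with
#'   \code{comparisons} (per-pair list: fit, outliers), \code{union}
#'   (data.frame heptamer / n_comparisons / comparisons /
#'   max_abs_residual), \code{residualMatrix} (heptamer x dataset
#'   residuals vs mean, plus \code{invitro} column = in vitro vs mean),
#'   \code{tables}.
#' @export
runAllComparisons <- function(lineTables, invitroTable = NULL, topN = 20L) {
    tables <- lineTables
    tables$mean <- meanRateTable(lineTables)
    if (!is.null(invitroTable)) tables$invitro <- invitroTable
    labs <- names(tables)
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) {
        fit <- pairwiseResiduals(tables[[pr[1]]], tables[[pr[2]]])
        list(pair = pr, fit = fit,
             outliers = selectOutliers(fit, n = topN))
    })
    names(comparisons) <- vapply(pairs, paste, character(1), collapse = "_vs_")

    allOut <- do.call(rbind, lapply(names(comparisons), function(nm) {
        o <- comparisons[[nm]]$outliers
        o$comparison <- nm
        o
    }))
    un <- split(allOut, allOut$heptamer)
    union <- do.call(rbind, lapply(un, function(d) data.frame(
        heptamer = d$heptamer[1], n_comparisons = nrow(d),
        comparisons = paste(sort(d$comparison), collapse = ","),
        max_abs_residual = max(abs(d$residual)), stringsAsFactors = FALSE)))
    union <- union[order(union$heptamer), , drop = FALSE]
    rownames(union) <- NULL

    # published layout: each line's residual versus the mean of lines, and
    # the in vitro residual versus the mean of lines, over union heptamers
    cols <- names(lineTables)
    if (!is.null(invitroTable)) cols <- c(cols, "invitro")
    rm <- vapply(cols, function(lb) {
        fit <- pairwiseResiduals(tables$mean, tables[[lb]])
        fit$residuals[union$heptamer]
    }, numeric(nrow(union)))
    rownames(rm) <- union$heptamer

    structure(list(comparisons = comparisons, union = union,
                   residualMatrix = rm, tables = tables),
              class = c("OutlierReport", "list"))
}

#' Midpoint density profile centred on a heptamer
#'
#' Aggregates midpoint counts at every offset in \code{-flank..+flank}
#' from the central base of each occurrence of the heptamer (occurrences
#' without a full window are dropped) and reports the mean midpoint
#' density per occurrence per bp, optionally smoothed as in
#' [aggregateTss()].
#'
#' @param track a [MidpointTrack-class].
#' @param occurrences a \code{"KmerOccurrences"}.
#' @param heptamer the word to centre on.
#' @param flank half-window in bp (200 for the local view, 2000 for
#'   long-range ordering).
#' @param smooth smoothing window in bp (0 = none).
#' @return list with \code{offsets}, \code{density},
#'   \code{n_occurrences}, \code{genome_mean} (genome-wide mean midpoint
#'   density per bp, for reference), \code{heptamer}.
#' @export
heptamerCenteredProfile <- function(track, occurrences, heptamer,
                                    flank = 200L, smooth = 0L) {
    k <- occurrences$k
    centerOff <- (k - 1L) %/% 2L
    acc <- numeric(2L * flank + 1L)
    used <- 0L
    for (cn in names(occurrences$index)) {
        pos <- occurrencePositions(occurrences, heptamer, cn)
        if (!length(pos)) next
        x <- track@counts[[cn]]
        L <- length(x)
        ctr <- pos + centerOff
        ok <- ctr - flank >= 1L & ctr + flank <= L
        ctr <- ctr[ok]
        for (c0 in ctr) acc <- acc + x[(c0 - flank):(c0 + flank)]
        used <- used + length(ctr)
    }
    if (used == 0L)
        stopf("heptamer %s has no usable occurrence", heptamer)
    dens <- acc / used
    if (smooth > 1L) dens <- movingAverage(dens, smooth)
    genomeMean <- track@totalFragments / sum(as.numeric(track@seqlengths))
    list(offsets = (-flank):flank, density = dens, n_occurrences = used,
         genome_mean = genomeMean, heptamer = heptamer)
}
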