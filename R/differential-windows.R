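# Genome-wide fixed-window comparison of nucleosome occupancy.

#' Midpoint counts and FPKM over non-overlapping windows
#'
#' Tiles each chromosome with non-overlapping windows of \code{window} bp
#' starting at coordinate 0, counts midpoints per tile, and computes the
#' window FPKM: \code{count / (width / 1000) / (totalFragments / 1e6)}.
#' The trailing partial window (if any) is included, length-adjusted, and
#' flagged.
#'
#' @param track a [MidpointTrack-class].
#' @param window tile width in bp (default 200).
#' @return data.frame with \code{chrom}, \code{start} (0-based, multiple
#'   of \code{window}), \code{end}, \code{width}, \code{count},
#'   \code{fpkm}, \code{partial}.
#' @export
windowCounts <- function(track, window = 200L) {
    window <- as.integer(window)
    out <- lapply(names(track@counts), function(cn) {
        x <- track@counts[[cn]]
        L <- length(x)
        nwin <- ceiling(L / window)
        idx <- rep(seq_len(nwin), each = window, length.out = L)
        cnt <- as.vector(rowsum(x, idx))
        start0 <- (seq_len(nwin) - 1L) * window
        end0 <- pmin(start0 + window, L)
        w <- end0 - start0
        data.frame(chrom = cn, start = start0, end = end0, width = w,
                   count = cnt,
                   fpkm = cnt / (w / 1000) / (track@totalFragments / 1e6),
                   partial = w < window, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Differential occupancy calls over paired window tables
#'
#' For each window, tests whether the midpoint count in dataset a differs
#' from dataset b beyond library-size expectation, using a two-sided
#' conditional binomial test: given \code{n = count_a + count_b}, under
#' the null \code{count_a ~ Binomial(n, total_a / (total_a + total_b))}.
#' P-values are Benjamini-Hochberg adjusted across all windows with
#' \code{n > 0} (windows empty in both datasets are untestable and
#' excluded from testing, though kept in the table). A window is called
#' when \code{q < fdr} \emph{and} the FPKM fold change (with pseudocount
#' 0.5 added to both counts) exceeds \code{fold}. The Pearson correlation
#' is computed on \code{log10} pseudocounted FPKM pairs.
#'
#' @param a,b window tables from [windowCounts()] with identical tiling.
#' @param totalA,totalB library sizes (retained fragments); default taken
#'   from the tables' counts... must be supplied when tables are subsets.
#' @param fold fold-change threshold (default 2).
#' @param fdr FDR threshold (default 0.01).
#' @return object of class \code{"WindowComparison"}: list with
#'   \code{windows} (per-window data.frame: counts, FPKMs, fold, p, q,
#'   call), \code{pearson_r}, \code{n_called}, \code{n_tested},
#'   \code{fold_threshold}, \code{fdr_threshold}.
#' @export
compareWindows <- function(a, b, totalA = sum(a$count), totalB = sum(b$count),
                           fold = 2, fdr = 0.01) {
    if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
        !all(a$start == b$start) || !all(a$width == b$width))
        stopf("window tables have mismatched tilings")
    ca <- a$count
    cb <- b$count
    n <- ca + cb
    pnull <- totalA / (totalA + totalB)
    p <- rep(NA_real_, length(n))
    testable <- n > 0L
    p[testable] <- vapply(which(testable), function(i)
        stats::binom.test(ca[i], n[i], pnull)$p.value, numeric(1))
    q <- rep(NA_real_, length(n))
    q[testable] <- stats::p.adjust(p[testable], method = "BH")

    fa <- (ca + 0.5) / (a$width / 1000) / (totalA / 1e6)
    fb <- (cb + 0.5) / (b$width / 1000) / (totalB / 1e6)
    ratio <- pmax(fa / fb, fb / fa)
    call <- rep("unchanged", length(n))
    sig <- testable & !is.na(q) & q < fdr & ratio > fold
    call[sig & fa > fb] <- "enriched_in_a"
    call[sig & fb > fa] <- "enriched_in_b"

    windows <- data.frame(
        chrom = a$chrom, start = a$start, end = a$end, width = a$width,
        count_a = ca, count_b = cb, fpkm_a = a$fpkm, fpkm_b = b$fpkm,
        fold = ratio, p = p, q = q, call = call, stringsAsFactors = FALSE)
    structure(list(
        windows = windows,
        pearson_r = stats::cor(log10(fa), log10(fb), method = "pearson"),
        n_called = sum(sig), n_tested = sum(testable),
        fold_threshold = fold, fdr_threshold = fdr,
        total_a = totalA, total_b = totalB),
        class = c("WindowComparison", "list"))
}

#' Write called differential windows as BED
#'
#' @param comparison result of [compareWindows()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCalledWindowsBed <- function(comparison, path) {
    w <- comparison$windows
    w <- w[w$call != "unchanged", , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%g", w$chrom, w$start, w$end,
                       w$call, -log10(pmax(w$q, 1e-300))), path)
    invisible(path)
}
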