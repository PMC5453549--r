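#' @importFrom Biostrings width writeXStringSet readDNAStringSet
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Load paired nucleosome fragments
#'
#' Reads fragments from BEDPE (pair span), BED (precomputed fragment
#' intervals) or coordinate-sorted BAM. For BAM, proper primary pairs are
#' reconstructed from template length: one fragment per pair spanning
#' \code{[pos, pos + TLEN)} of the leftmost mate; unmapped, secondary and
#' supplementary records are dropped. \code{mapq_unique} is set from
#' mapping quality >= \code{mapqThreshold} (BEDPE/BED use the score column
#' when present, otherwise fragments are taken as uniquely mapped).
#'
#' @param path input file.
#' @param format one of \code{"bedpe"}, \code{"bed"}, \code{"bam"}
#'   (default guessed from the file extension).
#' @param mapqThreshold minimum mapping quality regarded as unique.
#' @param seqlengths optional named chromosome lengths; fragments on
#'   chromosomes absent from it raise an error listing the offenders.
#' @return a [GenomicRanges::GRanges-class] with mcols \code{mapq} and
#'   \code{mapq_unique}.
#' @export
loadFragments <- function(path, format = c("auto", "bedpe", "bed", "bam"),
                          mapqThreshold = 20L, seqlengths = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, bam = "bam", bedpe = "bedpe", bed = "bed",
                         stopf("cannot guess format from extension '%s'", ext))
    }
    if (!file.exists(path)) stopf("file not found: %s", path)
    gr <- switch(format,
                 bedpe = loadBedpe(path, mapqThreshold),
                 bed = loadBed(path, mapqThreshold),
                 bam = loadBamPairs(path, mapqThreshold))
    if (!is.null(seqlengths)) {
        bad <- setdiff(unique(as.character(seqnames(gr))), names(seqlengths))
        if (length(bad))
            stopf("chromosome(s) absent from genome: %s",
                  paste(bad, collapse = ", "))
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr
}

loadBedpe <- function(path, mapqThreshold) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(emptyFragments())
    f <- strsplit(lines, "[ \t]+")
    nf <- lengths(f)
    bad <- which(nf < 6L)
    if (length(bad))
        stopf("malformed BEDPE record at line %d (fewer than 6 fields)", bad[1])
    m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6, byrow = TRUE)
    s1 <- suppressWarnings(as.integer(m[, 2]))
    e1 <- suppressWarnings(as.integer(m[, 3]))
    s2 <- suppressWarnings(as.integer(m[, 5]))
    e2 <- suppressWarnings(as.integer(m[, 6]))
    bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
    if (length(bad))
        stopf("malformed BEDPE record at line %d (non-integer coordinates)",
              bad[1])
    bad <- which(m[, 1] != m[, 4])
    if (length(bad))
        stopf("malformed BEDPE record at line %d (interchromosomal pair)",
              bad[1])
    score <- vapply(f, function(x)
        if (length(x) >= 8L) suppressWarnings(as.numeric(x[8])) else NA_real_,
        numeric(1))
    mapq <- ifelse(is.na(score), 60, score)
    gr <- GRanges(m[, 1], IRanges(pmin(s1, s2) + 1L, pmax(e1, e2)))
    mcols(gr)$mapq <- as.integer(mapq)
    mcols(gr)$mapq_unique <- mcols(gr)$mapq >= mapqThreshold
    gr
}

loadBed <- function(path, mapqThreshold) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                       !startsWith(lines, "track")]
    if (!length(lines))
        return(emptyFragments())
    f <- strsplit(lines, "[ \t]+")
    bad <- which(lengths(f) < 3L)
    if (length(bad))
        stopf("malformed BED record at line %d (fewer than 3 fields)", bad[1])
    chrom <- vapply(f, `[`, character(1), 1)
    s <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 2)))
    e <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 3)))
    bad <- which(is.na(s) | is.na(e))
    if (length(bad))
        stopf("malformed BED record at line %d (non-integer coordinates)",
              bad[1])
    score <- vapply(f, function(x)
        if (length(x) >= 5L) suppressWarnings(as.numeric(x[5])) else NA_real_,
        numeric(1))
    mapq <- ifelse(is.na(score), 60, score)
    gr <- GRanges(chrom, IRanges(s + 1L, e))
    mcols(gr)$mapq <- as.integer(mapq)
    mcols(gr)$mapq_unique <- mcols(gr)$mapq >= mapqThreshold
    gr
}

loadBamPairs <- function(path, mapqThreshold) {
    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
        isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flag, what = c("rname", "pos", "mapq", "isize"))
    res <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(res$isize) & res$isize > 0L
    if (!any(keep))
        return(emptyFragments())
    gr <- GRanges(as.character(res$rname[keep]),
                  IRanges(res$pos[keep], width = res$isize[keep]))
    mq <- res$mapq[keep]
    mq[is.na(mq)] <- 0L
    mcols(gr)$mapq <- mq
    mcols(gr)$mapq_unique <- mq >= mapqThreshold
    gr
}

emptyFragments <- function() {
    gr <- GRanges()
    mcols(gr)$mapq <- integer(0)
    mcols(gr)$mapq_unique <- logical(0)
    gr
}

#' Apply the mononucleosome retention filter
#'
#' Keeps uniquely mapped fragments with length between \code{minLength} and
#' \code{maxLength} bp, both bounds inclusive (default 101-191 bp, the
#' mononucleosome band). Record order is preserved and the operation is
#' idempotent. Positional deduplication of identical fragment coordinates
#' is available but off by default, since collapsing duplicates distorts
#' occupancy quantitation.
#'
#' @param gr fragments from [loadFragments()] or [sampleFragments()].
#' @param minLength,maxLength inclusive length bounds in bp.
#' @param dedup drop repeated (chrom, start, end) fragments, keeping the
#'   first.
#' @return the retained subset, same class and column layout.
#' @export
filterFragments <- function(gr, minLength = 101L, maxLength = 191L,
                            dedup = FALSE) {
    uq <- mcols(gr)$mapq_unique
    if (is.null(uq)) uq <- rep(TRUE, length(gr))
    keep <- uq & width(gr) >= minLength & width(gr) <= maxLength
    out <- gr[keep]
    if (dedup && length(out)) {
        key <- paste(as.character(seqnames(out)), start(out), end(out))
        out <- out[!duplicated(key)]
    }
    out
}

#' Build a dyad midpoint track from retained fragments
#'
#' Each fragment contributes one count at its midpoint,
#' \code{start + floor((length - 1) / 2)} (even lengths break the tie to
#' the lower coordinate). The total count equals the number of fragments.
#'
#' @param gr filtered fragments.
#' @param seqlengths named integer vector of chromosome lengths covering
#'   all fragments.
#' @param label dataset identifier stored in the track.
#' @return a [MidpointTrack-class].
#' @export
buildMidpointTrack <- function(gr, seqlengths, label = "dataset") {
    seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    mids <- start(gr) + (width(gr) - 1L) %/% 2L
    chrom <- as.character(seqnames(gr))
    bad <- setdiff(unique(chrom), names(seqlengths))
    if (length(bad))
        stopf("fragments on chromosome(s) not in seqlengths: %s",
              paste(bad, collapse = ", "))
    counts <- lapply(names(seqlengths), function(cn) {
        m <- mids[chrom == cn]
        stopifnot(all(m >= 1L & m <= seqlengths[[cn]]))
        tabulate(m, nbins = seqlengths[[cn]])
    })
    names(counts) <- names(seqlengths)
    new("MidpointTrack", counts = counts, seqlengths = seqlengths,
        totalFragments = as.numeric(length(gr)), sourceLabel = label)
}

#' Summarize retained fragment lengths
#'
#' @param gr fragments.
#' @return list with \code{mean}, \code{median}, and \code{histogram}
#'   (data.frame of length/count at 1-bp resolution; empty input yields
#'   NA summaries and an empty histogram).
#' @export
fragmentLengthSummary <- function(gr) {
    len <- width(gr)
    if (!length(len))
        return(list(mean = NA_real_, median = NA_real_,
                    histogram = data.frame(length = integer(0),
                                           count = integer(0))))
    tab <- table(len)
    list(mean = mean(len), median = stats::median(len),
         histogram = data.frame(length = as.integer(names(tab)),
                                count = as.integer(tab)))
}

#' Write a midpoint track as bedGraph
#'
#' Runs of equal counts are collapsed; coordinates follow the BED dialect
#' (0-based half-open). Zero-count runs are omitted.
#'
#' @param track a [MidpointTrack-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBedGraph <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s midpoints\"",
                       track@sourceLabel), con)
    for (cn in names(track@counts)) {
        x <- track@counts[[cn]]
        r <- rle(x)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values != 0L
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%d", cn, starts[keep] - 1L,
                           ends[keep], r$values[keep]), con)
    }
    invisible(path)
}

#' Write fragments as BEDPE
#'
#' Pairs are emitted as two 35-bp reads at the fragment ends, with the
#' fragment's mapping quality in the score column; coordinates are 0-based
#' half-open.
#'
#' @param gr fragments.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFragmentsBedpe <- function(gr, path) {
    rl <- pmin(35L, width(gr))
    mapq <- mcols(gr)$mapq
    if (is.null(mapq)) mapq <- rep(60L, length(gr))
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tfrag%d\t%d\t+\t-",
                     as.character(seqnames(gr)), start(gr) - 1L,
                     start(gr) - 1L + rl,
                     as.character(seqnames(gr)), end(gr) - rl, end(gr),
                     seq_along(gr), mapq)
    writeLines(lines, path)
    invisible(path)
}
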