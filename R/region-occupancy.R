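# Midpoint density by functional genomic region.

#' Partition the genome into promoter / exon / intron / intergenic
#'
#' Promoters are the union of windows from 500 bp upstream through 500 bp
#' downstream of each TSS, clipped to the chromosome. Overlapping bases
#' are resolved with precedence promoter > exon > intron > intergenic, so
#' the four labels are pairwise disjoint and jointly cover the genome.
#'
#' @param genes data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{tss} (e.g. from [readGeneModels()] or
#'   [geneModels()]).
#' @param exons data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param seqlengths named chromosome lengths.
#' @param promoterFlank bp on each side of the TSS (default 500).
#' @return object of class \code{"RegionPartition"}: list with
#'   \code{regions} (named [GenomicRanges::GRanges-class] list),
#'   \code{bp} (named base totals) and \code{seqlengths}.
#' @export
buildPartition <- function(genes, exons, seqlengths, promoterFlank = 500L) {
    seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    gspan <- genes[match(exons$gene_id, genes$gene_id), ]
    bad <- exons$start < gspan$start | exons$end > gspan$end
    if (any(bad))
        stopf("exon outside its gene span (gene %s)",
              exons$gene_id[which(bad)[1]])

    si <- GenomeInfoDb::Seqinfo(seqnames = names(seqlengths),
                                seqlengths = unname(seqlengths))
    mk <- function(chrom, s, e) {
        s <- pmax(s, 1L)
        e <- pmin(e, seqlengths[chrom])
        keep <- e >= s
        GenomicRanges::reduce(GenomicRanges::GRanges(
            chrom[keep], IRanges::IRanges(s[keep], e[keep]), seqinfo = si))
    }
    prom <- mk(genes$chrom, genes$tss - promoterFlank,
               genes$tss + promoterFlank - 1L)
    exAll <- mk(exons$chrom, exons$start, exons$end)
    body <- mk(genes$chrom, genes$start, genes$end)
    exonLab <- GenomicRanges::setdiff(exAll, prom)
    intronLab <- GenomicRanges::setdiff(
        GenomicRanges::setdiff(body, exAll), prom)
    covered <- GenomicRanges::reduce(c(prom, exonLab, intronLab))
    intergenic <- GenomicRanges::gaps(covered)
    intergenic <- intergenic[GenomicRanges::strand(intergenic) == "*"]
    regions <- list(promoter = prom, exon = exonLab, intron = intronLab,
                    intergenic = intergenic)
    bp <- vapply(regions, function(g) sum(as.numeric(GenomicRanges::width(g))),
                 numeric(1))
    structure(list(regions = regions, bp = bp, seqlengths = seqlengths),
              class = c("RegionPartition", "list"))
}

# sum of per-bp midpoint counts of `track` within GRanges `gr`
sumCountsInRanges <- function(track, gr) {
    tot <- 0
    for (cn in names(track@counts)) {
        sub <- gr[GenomicRanges::seqnames(gr) == cn]
        if (!length(sub)) next
        cs <- cumsum(c(0, track@counts[[cn]]))
        tot <- tot + sum(cs[GenomicRanges::end(sub) + 1L] -
                             cs[GenomicRanges::start(sub)])
    }
    tot
}

#' Midpoint density per genomic region
#'
#' Counts midpoints within each label of the partition and normalizes per
#' bp of the label and per million retained fragments:
#' \code{density = (midpoints / bp) / (totalFragments / 1e6)}. Raw counts
#' and per-million-only values (no length normalization) are also
#' returned; labels covering zero bases get \code{NA} density.
#'
#' @param track a [MidpointTrack-class].
#' @param partition result of [buildPartition()].
#' @return data.frame with one row per label: \code{region}, \code{bp},
#'   \code{midpoints}, \code{per_million} (midpoints x 1e6 / total),
#'   \code{density} (midpoints per bp per million fragments).
#' @export
regionDensity <- function(track, partition) {
    if (!identical(sort(names(partition$seqlengths)),
                   sort(names(track@seqlengths))))
        stopf("partition and track cover different chromosomes")
    labs <- names(partition$regions)
    counts <- vapply(labs, function(l)
        sumCountsInRanges(track, partition$regions[[l]]), numeric(1))
    bp <- partition$bp[labs]
    perM <- counts * 1e6 / track@totalFragments
    dens <- ifelse(bp > 0, (counts / bp) / (track@totalFragments / 1e6),
                   NA_real_)
    data.frame(region = labs, bp = unname(bp), midpoints = unname(counts),
               per_million = unname(perM), density = unname(dens),
               stringsAsFactors = FALSE)
}

#' Write a region partition as BED
#'
#' 0-based half-open intervals with the region label in the name column.
#'
#' @param partition result of [buildPartition()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePartitionBed <- function(partition, path) {
    rows <- character(0)
    for (lab in names(partition$regions)) {
        g <- partition$regions[[lab]]
        if (!length(g)) next
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s",
                                as.character(GenomicRanges::seqnames(g)),
                                GenomicRanges::start(g) - 1L,
                                GenomicRanges::end(g), lab))
    }
    writeLines(rows, path)
    invisible(path)
}
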