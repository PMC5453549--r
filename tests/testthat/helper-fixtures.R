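# Shared fixtures, built in code and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, expr, envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# small simulation for unit tests (50 kb, default energy model)
smallSim <- function() cached("smallSim", {
    p <- SimParams(genomeLength = 5e4, nGenes = 10L, motifCopies = 20L,
                   nFragmentsPerLine = 2e4, seed = 1)
    sim <- simulateGenome(p)
    sim$fragments <- lapply(c(eye = "eye", leg = "leg"), function(ln)
        sampleFragments(sim$genome, sim$truth, ln, 2e4))
    sim
})

smallTrack <- function(line = "eye") cached(paste0("smallTrack_", line), {
    sim <- smallSim()
    kept <- filterFragments(sim$fragments[[line]])
    buildMidpointTrack(kept, seqlengths(sim$genome), label = line)
})

# a hand-sized track: given midpoint positions on one chromosome
toyTrack <- function(positions, seqlen, chrom = "chr1", label = "toy") {
    counts <- list(tabulate(positions, nbins = seqlen))
    names(counts) <- chrom
    new("MidpointTrack", counts = counts,
        seqlengths = stats::setNames(as.integer(seqlen), chrom),
        totalFragments = length(positions), sourceLabel = label)
}

toyGenome <- function(seqs) {
    g <- Biostrings::DNAStringSet(unlist(seqs))
    names(g) <- names(seqs)
    g
}

# a SyntheticTruth wrapper for hand-built genomes (no genes, given motifs)
toyTruth <- function(params, motifPositions = NULL, lineMultipliers = list()) {
    if (is.null(motifPositions))
        motifPositions <- data.frame(chrom = character(0), start = integer(0),
                                     heptamer = character(0),
                                     stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), tss = integer(0),
                        expression = numeric(0), stringsAsFactors = FALSE)
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
    new("SyntheticTruth", motifPositions = motifPositions,
        lineMultipliers = lineMultipliers, genes = genes, exons = exons,
        params = params)
}

# paired-end SAM text: nPairs proper pairs plus nSecondary secondary records
writeSamFixture <- function(path, nPairs = 10L, nSecondary = 3L,
                            seqlen = 5000L, chrom = "chr1") {
    lines <- c(sprintf("@HD\tVN:1.6\tSO:coordinate"),
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, seqlen))
    pos <- seq(101L, by = 300L, length.out = nPairs)
    tlen <- 150L
    for (i in seq_len(nPairs)) {
        p1 <- pos[i]
        p2 <- p1 + tlen - 35L
        lines <- c(lines,
                   sprintf("p%d\t99\t%s\t%d\t60\t35M\t=\t%d\t%d\t*\t*",
                           i, chrom, p1, p2, tlen),
                   sprintf("p%d\t147\t%s\t%d\t60\t35M\t=\t%d\t%d\t*\t*",
                           i, chrom, p2, p1, -tlen))
    }
    for (i in seq_len(nSecondary)) {
        p1 <- pos[i] + 17L
        lines <- c(lines,
                   sprintf("s%d\t355\t%s\t%d\t0\t35M\t=\t%d\t%d\t*\t*",
                           i, chrom, p1, p1 + tlen - 35L, tlen))
    }
    # SAM records must be coordinate-sorted for asBam
    hdr <- lines[1:2]
    rec <- lines[-(1:2)]
    recPos <- as.integer(vapply(strsplit(rec, "\t"), `[`, character(1), 4))
    writeLines(c(hdr, rec[order(recPos)]), path)
    path
}
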