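test_that("generated genomes honour GC content, motif insertion and sizing", {
    p <- SimParams(genomeLength = 2e5, nGenes = 20L,
                   plantedMotifs = list(AATAATA = c(eye = 3)),
                   motifCopies = 30L, seed = 5)
    sim <- simulateGenome(p)
    g <- sim$genome
    # binomial bound: at L = 2e5, sd of GC fraction ~ sqrt(.43*.57/2e5) < 0.002
    gc <- sum(Biostrings::letterFrequency(g, "GC")) / sum(Biostrings::width(g))
    expect_gt(gc, 0.41)
    expect_lt(gc, 0.45)

    mp <- motifPositions(sim$truth)
    expect_equal(nrow(mp), 30L)
    for (i in seq_len(nrow(mp)))
        expect_identical(as.character(Biostrings::subseq(
            g[[mp$chrom[i]]], mp$start[i], mp$start[i] + 6L)), mp$heptamer[i])

    gm <- geneModels(sim$truth)
    expect_equal(nrow(gm), 20L)
    expect_false(any(duplicated(paste(gm$chrom, gm$tss))))
    ex <- exonModels(sim$truth)
    expect_true(all(ex$start >= gm$start[match(ex$gene_id, gm$gene_id)]))
    expect_true(all(ex$end <= gm$end[match(ex$gene_id, gm$gene_id)]))

    # planted motifs never overlap an exon-intron junction
    for (i in seq_len(nrow(mp))) {
        exc <- ex[ex$chrom == mp$chrom[i], ]
        gc2 <- gm[gm$chrom == mp$chrom[i], ]
        junctions <- setdiff(c(exc$start, exc$end + 1L),
                             c(gc2$start, gc2$end + 1L))
        expect_false(any(junctions >= mp$start[i] - 6L &
                             junctions <= mp$start[i] + 7L))
    }

    expect_error(simulateGenome(SimParams(genomeLength = 5000,
                                          nGenes = 10L, seed = 1)),
                 "too short")
})

test_that("identical seeds give byte-identical simulation outputs", {
    p <- SimParams(genomeLength = 2e4, nGenes = 4L, motifCopies = 5L,
                   nFragmentsPerLine = 500, seed = 42)
    d1 <- file.path(tempdir(), "simA")
    d2 <- file.path(tempdir(), "simB")
    s1 <- simulateDataset(p)
    s2 <- simulateDataset(p)
    writeSimulation(s1, d1)
    writeSimulation(s2, d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    }
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("placement energy follows the three-term model", {
    # on-phase vs off-phase: W/W dinucleotides at exact period-10 register
    # score higher (lower energy) than the same composition off-phase
    mkchrom <- function(shift) {
        b <- rep("G", 400)
        for (c0 in seq(200 - 70, 200 + 70, by = 10)) {
            b[c0 + shift] <- "A"
            b[c0 + shift + 1] <- "T"
        }
        paste(b, collapse = "")
    }
    p <- SimParams(periodicityWeight = 0.3, polyAPenalty = 0, seed = 1)
    gOn <- toyGenome(list(chr1 = mkchrom(0)))
    gOff <- toyGenome(list(chr1 = mkchrom(5)))
    tr <- toyTruth(p)
    eOn <- placementEnergy(gOn, "chr1", 200L, "eye", tr)
    eOff <- placementEnergy(gOff, "chr1", 200L, "eye", tr)
    expect_lt(eOn, eOff)

    # footprint fully inside a poly-A run, periodicity off: energy exceeds a
    # run-free footprint by exactly polyAPenalty * 147
    p2 <- SimParams(periodicityWeight = 0, polyAPenalty = 0.25, seed = 1)
    tr2 <- toyTruth(p2)
    gA <- toyGenome(list(chr1 = paste(rep("A", 400), collapse = "")))
    gMix <- toyGenome(list(chr1 = paste(rep("ACGT", 100), collapse = "")))
    eA <- placementEnergy(gA, "chr1", 200L, "eye", tr2)
    eMix <- placementEnergy(gMix, "chr1", 200L, "eye", tr2)
    expect_equal(eA - eMix, 0.25 * 147)

    # planted-motif multiplier lowers energy by log(multiplier) in its line
    gM <- toyGenome(list(chr1 = paste(rep("ACGT", 100), collapse = "")))
    trM <- toyTruth(p2, motifPositions = data.frame(
        chrom = "chr1", start = 197L, heptamer = "CGTACGT",
        stringsAsFactors = FALSE),
        lineMultipliers = list(X = c(CGTACGT = 3), Y = c(CGTACGT = 1)))
    eX <- placementEnergy(gM, "chr1", 200L, "X", trM)
    eY <- placementEnergy(gM, "chr1", 200L, "Y", trM)
    expect_equal(eY - eX, log(3))

    # footprint outside the sequence errors
    expect_error(placementEnergy(gM, "chr1", 50L, "X", trM), "outside")
})

test_that("flat-energy sampling is uniform (chi-square over seeded runs)", {
    p <- SimParams(genomeLength = 2e4, nGenes = 0L, plantedMotifs = list(),
                   periodicityWeight = 0, polyAPenalty = 0,
                   nFragmentsPerLine = 2000, seed = 1)
    sim <- simulateGenome(p)
    L <- 2e4
    lo <- 111L
    hi <- L - 110L
    breaks <- seq(lo - 0.5, hi + 0.5, length.out = 21L)
    rejected <- 0L
    for (s in 1:100) {
        fr <- sampleFragments(sim$genome, sim$truth, "eye", 2000, seed = s)
        dy <- GenomicRanges::start(fr) +
            (GenomicRanges::width(fr) - 1L) %/% 2L
        ct <- table(cut(dy, breaks))
        pval <- suppressWarnings(stats::chisq.test(as.vector(ct))$p.value)
        if (pval < 0.01) rejected <- rejected + 1L
    }
    expect_lte(rejected, 5L)
})

test_that("sampler output is deterministic, exact-count, and motif-responsive", {
    sim <- smallSim()
    g <- sim$genome
    f1 <- sampleFragments(g, sim$truth, "eye", 1000, seed = 9)
    f2 <- sampleFragments(g, sim$truth, "eye", 1000, seed = 9)
    expect_identical(as.data.frame(f1), as.data.frame(f2))
    expect_equal(length(f1), 1000L)
    expect_equal(length(sampleFragments(g, sim$truth, "eye", 0)), 0L)
    expect_true(all(GenomicRanges::width(f1) >= 80 &
                        GenomicRanges::width(f1) <= 220))

    # coverage over planted motif bases in the boosted line exceeds the
    # neutral line; ratio near the multiplier (3) at n = 1e5
    p <- SimParams(seed = 1)
    big <- simulateGenome(p)
    fx <- sampleFragments(big$genome, big$truth, "eye", 1e5)
    fy <- sampleFragments(big$genome, big$truth, "leg", 1e5)
    sl <- seqlengths(big$genome)
    cx <- coverageTrack(fx, sl)
    cy <- coverageTrack(fy, sl)
    mp <- motifPositions(big$truth)
    motifMean <- function(cov) {
        v <- 0
        for (i in seq_len(nrow(mp)))
            v <- v + mean(cov$depth[[mp$chrom[i]]][mp$start[i]:(mp$start[i] + 6L)])
        v / nrow(mp)
    }
    ratio <- motifMean(cx) / motifMean(cy)
    expect_gt(ratio, 3 * 0.75)
    expect_lt(ratio, 3 * 1.25)
})

test_that("simulation round-trips through the on-disk formats", {
    p <- SimParams(genomeLength = 3e4, nGenes = 5L, motifCopies = 8L,
                   nFragmentsPerLine = 800,
                   lines = c("eye", "invitro"), seed = 13)
    sim <- simulateDataset(p)
    d <- file.path(tempdir(), "simRT")
    paths <- writeSimulation(sim, d)

    g2 <- Biostrings::readDNAStringSet(paths[["genome"]])
    names(g2) <- sub("\\s.*$", "", names(g2))
    expect_identical(as.character(g2), as.character(sim$genome))

    ann <- readGeneModels(paths[["annotation"]])
    gm <- geneModels(sim$truth)
    expect_equal(ann$genes$tss[match(gm$gene_id, ann$genes$gene_id)], gm$tss)
    expect_equal(nrow(ann$exons), nrow(exonModels(sim$truth)))

    p2 <- readSimParams(paths[["params"]])
    expect_equal(p2@seed, p@seed)
    expect_equal(p2@plantedMotifs, p@plantedMotifs)

    fr <- loadFragments(paths[["eye"]], seqlengths = seqlengths(sim$genome))
    expect_equal(length(fr), length(sim$fragments$eye))
    expect_equal(GenomicRanges::start(fr), GenomicRanges::start(sim$fragments$eye))
    expect_equal(GenomicRanges::end(fr), GenomicRanges::end(sim$fragments$eye))
    unlink(d, recursive = TRUE)
})
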