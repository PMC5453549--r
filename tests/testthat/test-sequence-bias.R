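test_that("phasogram frequencies match hand-checkable cases", {
    # all-A genome: every dinucleotide is in the A/T class
    g <- toyGenome(list(chr1 = paste(rep("A", 400), collapse = "")))
    tr <- toyTrack(c(150L, 200L), 400L)
    ph <- computePhasogram(tr, g)
    expect_true(all(ph$ww_freq == 1))
    expect_true(all(ph$ss_freq == 0))
    expect_equal(ph$n_midpoints_used, 2)

    # single midpoint: 0/1 indicators recomputable by hand
    set.seed(4)
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    g2 <- toyGenome(list(chr1 = s))
    tr2 <- toyTrack(200L, 400L)
    ph2 <- computePhasogram(tr2, g2)
    b <- strsplit(s, "")[[1]]
    for (i in c(1, 50, 74, 100, 147)) {
        d <- paste0(b[200 + ph2$offsets[i]], b[200 + ph2$offsets[i] + 1])
        expect_equal(ph2$ww_freq[i],
                     as.numeric(d %in% c("AA", "AT", "TA", "TT")))
        expect_equal(ph2$ss_freq[i],
                     as.numeric(d %in% c("CC", "CG", "GC", "GG")))
    }

    # boundary midpoints are skipped and counted; none usable errors
    trEdge <- toyTrack(c(10L, 200L), 400L)
    phE <- computePhasogram(trEdge, g2)
    expect_equal(phE$n_skipped, 1)
    expect_error(computePhasogram(toyTrack(10L, 400L), g2), "usable")
})

test_that("phasogram equals the nested-loop oracle and is RC-symmetric", {
    sim <- smallSim()
    tr <- smallTrack()
    # thin the track to keep the oracle tractable
    cnt <- midpointCounts(tr)[[1]]
    pos <- which(cnt > 0)[seq(1, sum(cnt > 0), by = 37)]
    thin <- toyTrack(rep(pos, cnt[pos]), length(cnt),
                     chrom = names(midpointCounts(tr))[1])
    ph <- computePhasogram(thin, sim$genome)
    orc <- oraclePhasogram(thin, sim$genome)
    expect_equal(ph$ww_freq, orc$ww_freq, tolerance = 1e-12)
    expect_equal(ph$ss_freq, orc$ss_freq, tolerance = 1e-12)
    expect_equal(ph$n_midpoints_used, orc$n_midpoints_used)

    # reverse-complement the genome, mirror the midpoints: profile reverses.
    # With dinucleotides indexed by their start, the mirror of midpoint m
    # under reverse complementation is L - m.
    L <- length(cnt)
    rcG <- Biostrings::reverseComplement(sim$genome)
    mirrored <- toyTrack(rep(L - pos, cnt[pos]), L,
                         chrom = names(midpointCounts(tr))[1])
    phRC <- computePhasogram(mirrored, rcG)
    expect_equal(phRC$ww_freq, rev(ph$ww_freq), tolerance = 1e-12)
    expect_equal(phRC$ss_freq, rev(ph$ss_freq), tolerance = 1e-12)
})

test_that("k-mer genome frequencies are exact on enumerable genomes", {
    expect_equal(unname(kmerGenomeFrequency(toyGenome(list(c1 = "AAAA")), 2)["AA"]),
                 1)
    expect_equal(sum(kmerGenomeFrequency(toyGenome(list(c1 = "AAAA")), 2) > 0),
                 1L)
    P <- kmerGenomeFrequency(toyGenome(list(c1 = "ACGTACGT")), 3)
    expect_equal(length(P), 64L)
    orc <- oracleKmerGenomeFrequency(toyGenome(list(c1 = "ACGTACGT")), 3)
    expect_equal(P, orc)
    expect_equal(length(kmerGenomeFrequency(smallSim()$genome, 5)), 1024L)
    expect_error(kmerGenomeFrequency(toyGenome(list(c1 = "ACG")), 5),
                 "shorter")
    # ambiguous windows are skipped
    Pn <- kmerGenomeFrequency(toyGenome(list(c1 = "AANAA")), 2)
    expect_equal(unname(Pn["AA"]), 1)
})

test_that("nucleosomal k-mer frequencies are weighted and oracle-exact", {
    g <- toyGenome(list(c1 = paste(rep("C", 400), collapse = "")))
    f <- kmerNucleosomeFrequency(toyTrack(200L, 400L, chrom = "c1"), g, 5)
    expect_equal(unname(f["CCCCC"]), 1)

    # doubling every midpoint count leaves frequencies unchanged
    sim <- smallSim()
    cnt <- midpointCounts(smallTrack())[[1]]
    pos <- which(cnt > 0)[seq(1, sum(cnt > 0), by = 53)]
    t1 <- toyTrack(rep(pos, cnt[pos]), length(cnt),
                   chrom = names(seqlengths(sim$genome))[1])
    t2 <- toyTrack(rep(pos, 2L * cnt[pos]), length(cnt),
                   chrom = names(seqlengths(sim$genome))[1])
    f1 <- kmerNucleosomeFrequency(t1, sim$genome, 3)
    f2 <- kmerNucleosomeFrequency(t2, sim$genome, 3)
    expect_equal(f1, f2, tolerance = 1e-12)
    expect_equal(sum(f1), 1, tolerance = 1e-9)

    orc <- oracleKmerNucleosomeFrequency(t1, sim$genome, 3)
    expect_equal(f1, orc, tolerance = 1e-12)
})

test_that("log2 depletion statistic handles zeros and directions", {
    P <- c(A = 0.5, C = 0.25, G = 0.25, T = 0)
    expect_true(all(log2Depletion(P, P) == 0, na.rm = TRUE))
    Pn <- c(A = 0.25, C = 0.25, G = 0.5, T = 0)
    ld <- log2Depletion(P, Pn)
    expect_equal(unname(ld["A"]), 1)
    expect_true(is.na(ld["T"]))
    expect_error(log2Depletion(P, Pn[1:3]), "length")
})

test_that("pentamer classes partition as 32 / 32 / 1024", {
    sim <- smallSim()
    en <- kmerEnrichment(smallTrack(), sim$genome, k = 5)
    pc <- pentamerClassDistributions(en)
    expect_equal(length(pc$at_only$kmers), 32L)
    expect_equal(length(pc$gc_only$kmers), 32L)
    expect_equal(length(pc$all$kmers), 1024L)
    expect_true("AATAA" %in% pc$at_only$kmers)
    expect_false("ACGTA" %in% pc$at_only$kmers)
    expect_false("ACGTA" %in% pc$gc_only$kmers)
    expect_error(pentamerClassDistributions(list(k = 4L)), "k = 5")
})
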