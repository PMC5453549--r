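test_that("BEDPE pairs load as their spanning fragment", {
    f <- tempfile(fileext = ".bedpe")
    writeLines(c("chr1\t100\t150\tchr1\t200\t247\tp1\t60\t+\t-",
                 "chr1\t300\t335\tchr1\t260\t300\tp2\t10\t-\t+"), f)
    gr <- loadFragments(f)
    expect_equal(length(gr), 2L)
    # 0-based [100,247) span -> 1-based [101,247], length 147
    expect_equal(GenomicRanges::start(gr)[1], 101L)
    expect_equal(GenomicRanges::end(gr)[1], 247L)
    expect_equal(GenomicRanges::width(gr)[1], 147L)
    expect_identical(S4Vectors::mcols(gr)$mapq_unique, c(TRUE, FALSE))

    writeLines(character(0), f)
    expect_equal(length(loadFragments(f)), 0L)

    writeLines("chr1\t100\t150\tchr2\t200\t247\tp\t60\t+\t-", f)
    expect_error(loadFragments(f), "line 1")
    writeLines("chr1\tx\t150\tchr1\t200\t247", f)
    expect_error(loadFragments(f), "line 1")
    unlink(f)
})

test_that("BAM loading keeps proper primary pairs only", {
    sam <- tempfile(fileext = ".sam")
    writeSamFixture(sam, nPairs = 10L, nSecondary = 3L)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    gr <- loadFragments(bam)
    expect_equal(length(gr), 10L)
    expect_true(all(GenomicRanges::width(gr) == 150L))
    expect_true(all(S4Vectors::mcols(gr)$mapq_unique))
    expect_error(loadFragments(bam, seqlengths = c(chrX = 1000L)),
                 "chr1")
    unlink(c(sam, bam, paste0(bam, ".bai")))
})

test_that("retention filter applies inclusive bounds on unique fragments", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = 1000L, width = c(100L, 101L, 147L, 191L, 192L)))
    S4Vectors::mcols(gr)$mapq <- rep(60L, 5)
    S4Vectors::mcols(gr)$mapq_unique <- rep(TRUE, 5)
    kept <- filterFragments(gr)
    expect_equal(GenomicRanges::width(kept), c(101L, 147L, 191L))

    allMulti <- gr
    S4Vectors::mcols(allMulti)$mapq_unique <- rep(FALSE, 5)
    expect_equal(length(filterFragments(allMulti)), 0L)

    # idempotence and independent recount on simulated lengths
    sim <- smallSim()
    fr <- sim$fragments$eye[seq_len(1000)]
    kept <- filterFragments(fr)
    expect_identical(filterFragments(kept), kept)
    lens <- GenomicRanges::width(fr)
    expect_equal(length(kept), sum(lens >= 101 & lens <= 191))

    # dedup flag removes repeated coordinates only when asked
    dup <- c(gr[2], gr[2], gr[3])
    expect_equal(length(filterFragments(dup)), 3L)
    expect_equal(length(filterFragments(dup, dedup = TRUE)), 2L)
})

test_that("midpoint track follows the floor((len-1)/2) convention", {
    sl <- c(chr1 = 1000L)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101L, 101L), end = c(247L, 248L)))
    tr <- buildMidpointTrack(gr, sl)
    # 0-based fragment [100,247), len 147 -> midpoint 173 (1-based 174)
    # 0-based fragment [100,248), len 148 -> midpoint 173 (tie to lower)
    expect_equal(midpointCounts(tr)$chr1[174], 2L)
    expect_equal(sum(midpointCounts(tr)$chr1), 2)
    expect_equal(totalFragments(tr), 2)

    # conservation at scale, and round-trip with the sampler's endpoint rule
    sim <- smallSim()
    fr <- sampleFragments(sim$genome, sim$truth, "eye", 5000, seed = 3)
    tr2 <- buildMidpointTrack(fr, seqlengths(sim$genome))
    expect_equal(totalFragments(tr2), 5000)
    expect_equal(sum(vapply(midpointCounts(tr2), sum, numeric(1))), 5000)
})

test_that("fragment length summaries match direct computation", {
    mk <- function(lens) GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = 500L, width = lens))
    s <- fragmentLengthSummary(mk(c(147L, 147L, 147L)))
    expect_equal(s$mean, 147)
    expect_equal(s$median, 147)
    s2 <- fragmentLengthSummary(mk(c(101L, 191L)))
    expect_equal(s2$mean, 146)
    expect_equal(s2$median, 146)
    expect_equal(s2$histogram$count, c(1L, 1L))
    s3 <- fragmentLengthSummary(GenomicRanges::GRanges())
    expect_true(is.na(s3$mean))
    expect_equal(nrow(s3$histogram), 0L)

    # simulator defaults give mean near the mononucleosome length
    sim <- smallSim()
    kept <- filterFragments(sim$fragments$eye)
    s4 <- fragmentLengthSummary(kept)
    expect_gt(s4$mean, 144)
    expect_lt(s4$mean, 150)
})

test_that("bedGraph output round-trips the midpoint track", {
    tr <- toyTrack(c(5L, 5L, 9L), 20L)
    f <- tempfile(fileext = ".bedgraph")
    writeBedGraph(tr, f)
    lines <- readLines(f)
    expect_equal(lines[-1], c("chr1\t4\t5\t2", "chr1\t8\t9\t1"))
    unlink(f)
})
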