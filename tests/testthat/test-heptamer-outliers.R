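test_that("heptamer occurrence tables enumerate 4^7 words with overlaps", {
    occ <- heptamerOccurrences(toyGenome(list(c1 = "AAAAAAAA")))
    expect_equal(length(occ$counts), 16384L)
    expect_equal(unname(occ$counts["AAAAAAA"]), 2L)
    expect_equal(NucleoScope:::occurrencePositions(occ, "AAAAAAA", "c1"),
                 c(1L, 2L))

    sim <- smallSim()
    occ2 <- heptamerOccurrences(sim$genome)
    expect_equal(sum(occ2$counts),
                 sum(Biostrings::width(sim$genome) - 6L))
})

test_that("coverage depth equals the membership-count oracle", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101L, 150L, 900L), end = c(247L, 296L, 1046L)))
    cov <- coverageTrack(gr, c(chr1 = 2000L))
    expect_equal(cov$depth$chr1, oracleCoverage(gr, 2000L, "chr1"))
    expect_equal(sum(cov$depth$chr1), sum(GenomicRanges::width(gr)))
    # one fragment [100,247) 0-based: depth 1 exactly on [101,247] 1-based
    c1 <- coverageTrack(gr[1], c(chr1 = 2000L))
    expect_true(all(c1$depth$chr1[101:247] == 1L))
    expect_equal(sum(c1$depth$chr1), 147L)
})

test_that("heptamer rates match closed-form cases and the brute-force oracle", {
    # uniform depth c everywhere -> every present heptamer rate = c*1e6/total
    g <- toyGenome(list(c1 = paste(rep("ACGT", 250), collapse = "")))
    unif <- structure(list(
        depth = list(c1 = rep(3L, 1000L)), seqlengths = c(c1 = 1000L),
        totalFragments = 500), class = c("CoverageTrack", "list"))
    occ <- heptamerOccurrences(g)
    rt <- heptamerRates(unif, occ, label = "u")
    present <- !is.na(kmerRates(rt))
    expect_true(all(abs(kmerRates(rt)[present] - 3 * 1e6 / 500) < 1e-9))

    # rate tables are invariant under duplication of every fragment
    sim <- smallSim()
    fr <- filterFragments(sim$fragments$eye)[1:4000]
    sl <- seqlengths(sim$genome)
    occS <- heptamerOccurrences(sim$genome)
    r1 <- heptamerRates(coverageTrack(fr, sl), occS)
    r2 <- heptamerRates(coverageTrack(c(fr, fr), sl), occS)
    expect_equal(kmerRates(r1), kmerRates(r2), tolerance = 1e-12)

    # exact agreement with the nested-loop oracle on a small genome
    p <- SimParams(genomeLength = 6000, nGenes = 1L, motifCopies = 3L,
                   nFragmentsPerLine = 300, seed = 2)
    simS <- simulateGenome(p)
    frS <- sampleFragments(simS$genome, simS$truth, "eye", 300)
    occT <- heptamerOccurrences(simS$genome)
    rImpl <- heptamerRates(coverageTrack(frS, seqlengths(simS$genome)), occT)
    rOrc <- oracleHeptamerRates(frS, simS$genome)
    expect_equal(kmerRates(rImpl), rOrc, tolerance = 1e-9)
})

test_that("OLS residuals agree with the normal-equations oracle", {
    mkTab <- function(rates, label) new("KmerRateTable", label = label,
        k = 7L, occurrences = stats::setNames(rep(1L, 16384),
                                              NucleoScope:::allKmers(7)),
        rates = stats::setNames(rates, NucleoScope:::allKmers(7)),
        totalFragments = 1e5)
    set.seed(9)
    x <- stats::rlnorm(16384)
    tA <- mkTab(x, "a")
    same <- pairwiseResiduals(tA, tA)
    expect_equal(same$slope, 1)
    expect_equal(same$intercept, 0, tolerance = 1e-12)
    expect_true(all(abs(same$residuals) < 1e-10))
    doubled <- pairwiseResiduals(tA, mkTab(2 * x, "b"))
    expect_equal(doubled$slope, 2)
    expect_true(all(abs(doubled$residuals) < 1e-9))

    y <- pmax(0.7 * x + stats::rnorm(16384, sd = 0.3), 0)
    fit <- pairwiseResiduals(tA, mkTab(y, "c"))
    # closed-form normal equations
    n <- length(x)
    sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
    ic <- mean(y) - sl * mean(x)
    expect_equal(fit$slope, sl, tolerance = 1e-10)
    expect_equal(fit$intercept, ic, tolerance = 1e-10)
    expect_equal(unname(fit$residuals), y - (ic + sl * x), tolerance = 1e-10)
})

test_that("outlier selection is a deterministic top-N by |residual|", {
    set.seed(10)
    r <- stats::setNames(stats::rnorm(16384), NucleoScope:::allKmers(7))
    out <- selectOutliers(r, 20)
    expect_equal(nrow(out), 20L)
    srt <- names(sort(-abs(r)))[1:20]
    expect_setequal(out$heptamer, srt)

    zero <- stats::setNames(rep(0, 100), sprintf("K%03d", 1:100))
    expect_identical(selectOutliers(zero, 20)$heptamer,
                     sprintf("K%03d", 1:20))
    expect_error(selectOutliers(c(a = NA_real_)), "finite")
})

test_that("the full screen runs 15 comparisons and recovers planted motifs", {
    sim <- smallSim()
    occ <- heptamerOccurrences(sim$genome)
    sl <- seqlengths(sim$genome)
    mk <- function(ln, n, seed) {
        fr <- filterFragments(sampleFragments(sim$genome, sim$truth, ln, n,
                                              seed = seed))
        heptamerRates(coverageTrack(fr, sl), occ, label = ln)
    }
    lines <- list(antenna = mk("antenna", 8000, 1), eye = mk("eye", 8000, 2),
                  haltere = mk("haltere", 8000, 3), leg = mk("leg", 8000, 4))
    invitro <- mk("invitro", 8000, 5)
    rep <- runAllComparisons(lines, invitro)
    expect_equal(length(rep$comparisons), 15L)
    expect_true(all(vapply(rep$comparisons,
                           function(cc) nrow(cc$outliers), numeric(1)) == 20))
    expect_lte(nrow(rep$union), 300L)
    expect_equal(colnames(rep$residualMatrix),
                 c("antenna", "eye", "haltere", "leg", "invitro"))

    # six identical tables: residuals vanish, union is set by the tie rule
    same <- runAllComparisons(list(a = lines$antenna, b = lines$antenna,
                                   c = lines$antenna, d = lines$antenna),
                              lines$antenna)
    expect_equal(length(same$comparisons), 15L)
    expect_true(all(abs(same$residualMatrix) < 1e-9))
    lexFirst <- sort(names(kmerRates(lines$antenna))[
        !is.na(kmerRates(lines$antenna))])[1:20]
    expect_identical(same$union$heptamer, lexFirst)
})

test_that("heptamer-centred profiles reflect planted occupancy shifts", {
    g <- toyGenome(list(c1 = paste(rep("ACGT", 500), collapse = "")))
    occ <- heptamerOccurrences(g)
    # single midpoint on the central base of the ACGTACG occurrence at 997
    tr <- toyTrack(1000L, 2000L, chrom = "c1")
    pr <- heptamerCenteredProfile(tr, occ, "ACGTACG", flank = 50)
    expect_equal(pr$density[pr$offsets == 0] > 0, TRUE)

    sim <- smallSim()
    occS <- heptamerOccurrences(sim$genome)
    trE <- smallTrack("eye")   # AATAATA boosted x3 in this line
    trL <- smallTrack("leg")
    pE <- heptamerCenteredProfile(trE, occS, "AATAATA", flank = 200)
    pL <- heptamerCenteredProfile(trL, occS, "AATAATA", flank = 200)
    core <- abs(pE$offsets) <= 100
    expect_gt(mean(pE$density[core]), pE$genome_mean)
    expect_gt(mean(pE$density[core]), mean(pL$density[core]))
    expect_error(heptamerCenteredProfile(trE, occS, "NNNNNNN"), "not a valid")
})
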