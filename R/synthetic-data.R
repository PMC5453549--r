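#' Construct simulation parameters
#'
#' User-facing constructor for [SimParams-class]. Defaults describe the
#' study conditions emulated throughout the package: a 200-kb single
#' chromosome at Drosophila-like 43% GC, 50 genes, 2e5 fragments per
#' dataset with truncated-normal lengths centred on 147 bp, a 10-bp phased
#' A/T dinucleotide placement preference, poly(dA:dT) exclusion, promoter
#' architecture for in vivo lines, and one planted heptamer (AATAATA)
#' with a 3-fold occupancy multiplier in the "eye" line.
#'
#' @param genomeLength total genome length in bp.
#' @param nChromosomes number of chromosomes.
#' @param gcContent target G+C fraction.
#' @param nGenes number of gene models.
#' @param nFragmentsPerLine fragments sampled per dataset.
#' @param fragmentLengthMean,fragmentLengthSd truncated-normal length model
#'   (support [80, 220] bp).
#' @param periodicityWeight coefficient of the phased A/T dinucleotide
#'   energy term.
#' @param polyAPenalty energy per footprint base inside a poly(dA:dT) run
#'   of length >= 5.
#' @param plantedMotifs named list mapping heptamers to named numeric
#'   vectors of per-line occupancy multipliers.
#' @param motifCopies genomic copies planted per motif.
#' @param occupancyLoci list of region-level occupancy modifiers, each a
#'   list with \code{chrom}, \code{start}, \code{end} and
#'   \code{multipliers} (named numeric per line).
#' @param ndrWidth,ndrBarrier nucleosome-depleted-region width (bp) and
#'   energy barrier height upstream of each TSS.
#' @param phasingAmplitude,phasingDecay,nucleosomeSpacing,plusOneOffset
#'   downstream phased-array bonus: amplitude coefficient (scaled by
#'   \code{pmax(log10(FPKM), 0)} per gene), exponential decay length (bp),
#'   repeat length (bp), and +1 nucleosome dyad offset from the TSS (bp).
#' @param expressionLevels optional per-gene FPKM-like values (length
#'   \code{nGenes}); drawn log-normally from the seed when omitted.
#' @param lines dataset labels.
#' @param invitroLines lines simulated without promoter architecture
#'   (sequence-intrinsic placement only), emulating reconstituted chromatin.
#' @param seed integer seed; fully determines all outputs.
#' @return a validated [SimParams-class] object.
#' @examples
#' p <- SimParams(genomeLength = 50000, nGenes = 10, seed = 7)
#' p
#' @export
SimParams <- function(genomeLength = 2e5,
                      nChromosomes = 1L,
                      gcContent = 0.43,
                      nGenes = 50L,
                      nFragmentsPerLine = 2e5,
                      fragmentLengthMean = 147,
                      fragmentLengthSd = 20,
                      periodicityWeight = 0.05,
                      polyAPenalty = 0.25,
                      plantedMotifs = list(AATAATA = c(eye = 3)),
                      motifCopies = 80L,
                      occupancyLoci = list(),
                      ndrWidth = 150L,
                      ndrBarrier = 2,
                      phasingAmplitude = 1.2,
                      phasingDecay = 120,
                      nucleosomeSpacing = 175,
                      plusOneOffset = 75L,
                      expressionLevels = numeric(0),
                      lines = c("antenna", "eye", "haltere", "leg", "invitro"),
                      invitroLines = "invitro",
                      seed = 1L) {
    new("SimParams",
        genomeLength = as.numeric(genomeLength),
        nChromosomes = as.integer(nChromosomes),
        gcContent = gcContent,
        nGenes = as.integer(nGenes),
        nFragmentsPerLine = as.numeric(nFragmentsPerLine),
        fragmentLengthMean = fragmentLengthMean,
        fragmentLengthSd = fragmentLengthSd,
        periodicityWeight = periodicityWeight,
        polyAPenalty = polyAPenalty,
        plantedMotifs = plantedMotifs,
        motifCopies = as.integer(motifCopies),
        occupancyLoci = occupancyLoci,
        ndrWidth = as.integer(ndrWidth),
        ndrBarrier = ndrBarrier,
        phasingAmplitude = phasingAmplitude,
        phasingDecay = phasingDecay,
        nucleosomeSpacing = nucleosomeSpacing,
        plusOneOffset = as.integer(plusOneOffset),
        expressionLevels = as.numeric(expressionLevels),
        lines = lines,
        invitroLines = invitroLines,
        seed = as.integer(seed))
}

# chromosome lengths implied by params
chromLengths <- function(params) {
    n <- params@nChromosomes
    base <- floor(params@genomeLength / n)
    lens <- rep(base, n)
    lens[n] <- lens[n] + params@genomeLength - base * n
    stats::setNames(as.integer(lens), paste0("chrS", seq_len(n)))
}

#' Generate a synthetic genome, gene annotation and ground truth
#'
#' Draws random genome sequence at the requested GC content, places
#' non-overlapping gene models (1-3 exons each, random strand, unique
#' TSSs), plants heptamer motifs at recorded positions that never overlap
#' exon-intron junctions, and assigns per-gene expression levels.
#'
#' @param params a [SimParams-class] object.
#' @return list with elements \code{genome} (a
#'   [Biostrings::DNAStringSet-class]) and \code{truth}
#'   (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateGenome(SimParams(genomeLength = 30000, nGenes = 5,
#'                                 motifCopies = 10L, seed = 3))
#' sim$truth
#' @export
simulateGenome <- function(params) {
    validObject(params)
    set.seed(deriveSeed(params@seed, "genome"))
    lens <- chromLengths(params)
    gc <- params@gcContent
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- lapply(lens, function(L)
        paste(sample(names(probs), L, replace = TRUE, prob = probs),
              collapse = ""))

    # ---- gene placement ----------------------------------------------------
    nGenes <- params@nGenes
    genesPerChrom <- diff(floor(seq(0, nGenes, length.out = length(lens) + 1)))
    geneRows <- list()
    exonRows <- list()
    gid <- 0L
    minGap <- 400L
    for (ci in seq_along(lens)) {
        ng <- genesPerChrom[ci]
        if (ng == 0L) next
        L <- lens[ci]
        geneLens <- sample(2000:4000, ng, replace = TRUE)
        need <- sum(geneLens) + (ng + 1L) * minGap
        if (need > L)
            stopf("genome too short: chromosome %s (%d bp) cannot host %d genes (needs >= %d bp)",
                  names(lens)[ci], L, ng, need)
        slack <- L - need
        # random gap allocation; genes laid down left to right
        cuts <- sort(sample.int(slack + 1L, ng + 1L, replace = TRUE) - 1L)
        extra <- diff(c(0L, cuts))
        pos <- minGap + extra[1L]
        for (g in seq_len(ng)) {
            gid <- gid + 1L
            gstart <- pos + 1L
            gend <- gstart + geneLens[g] - 1L
            strand <- sample(c("+", "-"), 1L)
            tss <- if (strand == "+") gstart else gend
            nex <- sample(1:3, 1L)
            ex <- cutGeneIntoExons(gstart, gend, nex)
            geneRows[[gid]] <- data.frame(
                gene_id = sprintf("gene%03d", gid), chrom = names(lens)[ci],
                start = gstart, end = gend, strand = strand, tss = tss,
                stringsAsFactors = FALSE)
            exonRows[[gid]] <- data.frame(
                gene_id = sprintf("gene%03d", gid), chrom = names(lens)[ci],
                start = ex$start, end = ex$end, stringsAsFactors = FALSE)
            pos <- gend + minGap + extra[g + 1L]
        }
    }
    emptyGenes <- data.frame(gene_id = character(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             strand = character(0), tss = integer(0),
                             stringsAsFactors = FALSE)
    genes <- if (length(geneRows)) do.call(rbind, geneRows) else emptyGenes
    exons <- if (length(exonRows)) do.call(rbind, exonRows) else
        emptyGenes[, c("gene_id", "chrom", "start", "end")]
    expr <- params@expressionLevels
    if (!length(expr))
        expr <- signif(stats::rlnorm(nGenes, meanlog = 0.7, sdlog = 1.6), 4)
    genes$expression <- expr

    # ---- motif planting ----------------------------------------------------
    motifs <- names(params@plantedMotifs)
    motifPos <- data.frame(chrom = character(0), start = integer(0),
                           heptamer = character(0), stringsAsFactors = FALSE)
    if (length(motifs)) {
        # exclusion zones: exon-intron junctions +/- 6 bp (internal gene
        # boundaries only), plus previously planted motifs
        junctions <- lapply(names(lens), function(cn) {
            e <- exons[exons$chrom == cn, , drop = FALSE]
            g <- genes[genes$chrom == cn, , drop = FALSE]
            j <- setdiff(c(e$start, e$end + 1L), c(g$start, g$end + 1L))
            j
        })
        names(junctions) <- names(lens)
        occupied <- lapply(lens, function(L) logical(L))
        for (m in motifs) {
            placed <- 0L
            tries <- 0L
            while (placed < params@motifCopies) {
                tries <- tries + 1L
                if (tries > 200L * params@motifCopies)
                    stopf("genome too short to place %d copies of motif %s",
                          params@motifCopies, m)
                ci <- sample.int(length(lens), 1L)
                L <- lens[ci]
                p <- sample.int(L - 6L, 1L)
                win <- p:(p + 6L)
                jn <- junctions[[ci]]
                if (length(jn) && any(jn >= p - 6L & jn <= p + 7L)) next
                if (any(occupied[[ci]][win])) next
                occupied[[ci]][max(1L, p - 20L):min(L, p + 26L)] <- TRUE
                substr(seqs[[ci]], p, p + 6L) <- m
                motifPos <- rbind(motifPos, data.frame(
                    chrom = names(lens)[ci], start = p, heptamer = m,
                    stringsAsFactors = FALSE))
                placed <- placed + 1L
            }
        }
        motifPos <- motifPos[order(motifPos$chrom, motifPos$start), ,
                             drop = FALSE]
        rownames(motifPos) <- NULL
    }

    lineMult <- lapply(params@lines, function(ln) {
        v <- vapply(motifs, function(m) {
            mm <- params@plantedMotifs[[m]]
            if (ln %in% names(mm)) unname(mm[ln]) else 1
        }, numeric(1))
        names(v) <- motifs
        v
    })
    names(lineMult) <- params@lines

    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(lens)
    truth <- new("SyntheticTruth", motifPositions = motifPos,
                 lineMultipliers = lineMult, genes = genes, exons = exons,
                 params = params)
    list(genome = genome, truth = truth)
}

# split a gene span into nex exons separated by introns; all pieces >= 100 bp
cutGeneIntoExons <- function(gstart, gend, nex) {
    glen <- gend - gstart + 1L
    npieces <- 2L * nex - 1L
    if (glen < npieces * 100L) nex <- 1L
    if (nex == 1L)
        return(list(start = gstart, end = gend))
    npieces <- 2L * nex - 1L
    # piece lengths: 100 each plus random allocation of the remainder
    rem <- glen - npieces * 100L
    add <- as.vector(stats::rmultinom(1, rem, rep(1, npieces)))
    lens <- 100L + add
    ends <- gstart - 1L + cumsum(lens)
    starts <- c(gstart, ends[-npieces] + 1L)
    keep <- seq(1L, npieces, by = 2L)
    list(start = starts[keep], end = ends[keep])
}

# ---------------------------------------------------------------------------
# placement energy

FOOTPRINT <- 147L
FLANK <- 73L

# zero-sum period-10 kernel over dinucleotide offsets: rewards phased W/W
# placement but is neutral to uniform A/T content
phasedKernel <- function(offs) {
    k <- cos(2 * pi * offs / 10)
    k - mean(k)
}

# per-position sequence-intrinsic energy for one chromosome (NA where no
# full footprint fits); the three terms of the placement model:
#   -periodicityWeight * phased WW score
#   +polyAPenalty * (# footprint bases inside poly(dA:dT) runs >= 5)
#   -log(multiplier) where the footprint overlaps a planted motif
sequenceEnergyProfile <- function(seqchar, chromName, line, truth) {
    params <- truth@params
    L <- nchar(seqchar)
    E <- rep(NA_real_, L)
    if (L < FOOTPRINT) return(E)
    valid <- (FLANK + 1L):(L - FLANK)

    ww <- as.numeric(wwMask(seqchar))          # length L-1
    offs <- -FLANK:(FLANK - 1L)
    kern <- phasedKernel(offs)
    score <- numeric(length(valid))
    for (i in seq_along(offs)) {
        score <- score + kern[i] * ww[valid + offs[i]]
    }

    mask <- polyARunMask(seqchar)
    cs <- cumsum(c(0, mask))
    polyA <- cs[valid + FLANK + 1L] - cs[valid - FLANK]

    E[valid] <- -params@periodicityWeight * score + params@polyAPenalty * polyA

    mp <- truth@motifPositions
    mp <- mp[mp$chrom == chromName, , drop = FALSE]
    if (nrow(mp)) {
        mult <- truth@lineMultipliers[[line]]
        delta <- numeric(L + 1L)
        for (i in seq_len(nrow(mp))) {
            mu <- mult[[mp$heptamer[i]]]
            if (mu == 1) next
            lo <- max(FLANK + 1L, mp$start[i] - FLANK)
            hi <- min(L - FLANK, mp$start[i] + 6L + FLANK)
            if (lo > hi) next
            delta[lo] <- delta[lo] - log(mu)
            delta[hi + 1L] <- delta[hi + 1L] + log(mu)
        }
        E <- E + cumsum(delta)[seq_len(L)]
    }
    loci <- params@occupancyLoci
    if (length(loci)) {
        delta <- numeric(L + 1L)
        for (lc in loci) {
            if (lc$chrom != chromName) next
            mu <- unname(lc$multipliers[line])
            if (is.na(mu) || mu == 1) next
            lo <- max(1L, as.integer(lc$start))
            hi <- min(L, as.integer(lc$end))
            if (lo > hi) next
            delta[lo] <- delta[lo] - log(mu)
            delta[hi + 1L] <- delta[hi + 1L] + log(mu)
        }
        E <- E + cumsum(delta)[seq_len(L)]
    }
    E
}

# promoter-architecture energy for in vivo lines: NDR barrier upstream of
# each TSS plus a phased harmonic bonus over [0, +1000] downstream with an
# exponential distance decay, both scaled with expression so that weakly
# expressed genes show little promoter organization
promoterEnergyProfile <- function(L, chromName, truth) {
    params <- truth@params
    E <- numeric(L)
    g <- truth@genes[truth@genes$chrom == chromName, , drop = FALSE]
    if (!nrow(g)) return(E)
    for (i in seq_len(nrow(g))) {
        tss <- g$tss[i]
        strength <- max(log10(g$expression[i]), 0)
        amp <- params@phasingAmplitude * strength
        barrier <- params@ndrBarrier * min(1, strength / 2)
        if (g$strand[i] == "+") {
            lo <- max(1L, tss - params@ndrWidth)
            hi <- tss - 1L
            if (hi >= lo) E[lo:hi] <- E[lo:hi] + barrier
            dlo <- tss
            dhi <- min(L, tss + 1000L)
            rel <- (dlo:dhi) - tss
        } else {
            lo <- tss + 1L
            hi <- min(L, tss + params@ndrWidth)
            if (hi >= lo) E[lo:hi] <- E[lo:hi] + barrier
            dlo <- max(1L, tss - 1000L)
            dhi <- tss
            rel <- tss - (dlo:dhi)
        }
        if (amp > 0 && dhi >= dlo)
            E[dlo:dhi] <- E[dlo:dhi] -
                amp * exp(-rel / params@phasingDecay) *
                cos(2 * pi * (rel - params@plusOneOffset) /
                        params@nucleosomeSpacing)
    }
    E
}

#' Sequence-dependent nucleosome placement energy at one dyad position
#'
#' Evaluates the placement energy of a 147-bp nucleosome footprint centred
#' at \code{position}: a phased A/T dinucleotide bonus (period 10 bp,
#' registered to the dyad), a penalty per footprint base inside a
#' poly(dA:dT) run of length >= 5, and \code{-log(multiplier)} when the
#' footprint overlaps a planted motif with a non-unit multiplier in
#' \code{line}. Lower energy means a more favourable position. The promoter
#' architecture term used by [sampleFragments()] for in vivo lines is kept
#' separate (it is an annotation-, not sequence-, driven component).
#'
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param chrom chromosome name.
#' @param position 1-based dyad position; the footprint
#'   \code{[position-73, position+73]} must lie inside the chromosome.
#' @param line dataset label (selects the motif multipliers).
#' @param truth a [SyntheticTruth-class].
#' @return energy (dimensionless scalar).
#' @export
placementEnergy <- function(genome, chrom, position, line, truth) {
    if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
    seqchar <- as.character(genome[[chrom]])
    L <- nchar(seqchar)
    if (position - FLANK < 1L || position + FLANK > L)
        stopf("footprint around position %d extends outside %s (1..%d)",
              position, chrom, L)
    params <- truth@params

    ww <- wwMask(seqchar)
    offs <- -FLANK:(FLANK - 1L)
    score <- sum(phasedKernel(offs) * ww[position + offs])

    mask <- polyARunMask(seqchar)
    polyA <- sum(mask[(position - FLANK):(position + FLANK)])

    E <- -params@periodicityWeight * score + params@polyAPenalty * polyA

    mp <- truth@motifPositions
    mp <- mp[mp$chrom == chrom, , drop = FALSE]
    if (nrow(mp)) {
        mult <- truth@lineMultipliers[[line]]
        ov <- position >= mp$start - FLANK & position <= mp$start + 6L + FLANK
        for (i in which(ov)) E <- E - log(mult[[mp$heptamer[i]]])
    }
    E
}

#' Sample MNase-like fragments by Boltzmann placement
#'
#' Draws \code{n} nucleosome dyads with probability proportional to
#' \code{exp(-energy)} over all positions allowing a full fragment
#' (margin 110 bp from chromosome ends), where the energy is the
#' sequence-intrinsic placement energy plus, for in vivo lines, the
#' promoter architecture term. Fragment lengths are drawn from a normal
#' distribution truncated to [80, 220] bp and fragments are laid around
#' the dyad with the midpoint convention inverse to
#' [buildMidpointTrack()]: \code{start = dyad - floor((len-1)/2)}.
#'
#' @param genome a [Biostrings::DNAStringSet-class].
#' @param truth a [SyntheticTruth-class].
#' @param line dataset label.
#' @param n number of fragments; \code{n = 0} returns an empty set.
#' @param seed integer seed for this sampling stage (defaults to the
#'   simulation seed).
#' @return a coordinate-sorted [GenomicRanges::GRanges-class] with mcols
#'   \code{mapq} (60) and \code{mapq_unique} (TRUE).
#' @export
sampleFragments <- function(genome, truth, line, n,
                            seed = truth@params@seed) {
    params <- truth@params
    if (!line %in% params@lines) stopf("unknown line '%s'", line)
    n <- as.integer(n)
    margin <- 110L
    set.seed(deriveSeed(seed, "fragments", line))

    empty <- GenomicRanges::GRanges(
        seqnames = character(0), ranges = IRanges::IRanges(),
        seqlengths = stats::setNames(width(genome), names(genome)))
    S4Vectors::mcols(empty)$mapq <- integer(0)
    S4Vectors::mcols(empty)$mapq_unique <- logical(0)
    if (n <= 0L) return(empty)

    invitro <- line %in% params@invitroLines
    allChrom <- character(0)
    allPos <- integer(0)
    allW <- numeric(0)
    for (cn in names(genome)) {
        seqchar <- as.character(genome[[cn]])
        L <- nchar(seqchar)
        if (L < 2L * margin + 1L) next
        E <- sequenceEnergyProfile(seqchar, cn, line, truth)
        if (!invitro)
            E <- E + promoterEnergyProfile(L, cn, truth)
        valid <- (margin + 1L):(L - margin)
        Ev <- E[valid]
        w <- exp(-(Ev - min(Ev)))
        allChrom <- c(allChrom, rep(cn, length(valid)))
        allPos <- c(allPos, valid)
        allW <- c(allW, w)
    }
    if (!length(allPos)) stopf("no chromosome long enough to place fragments")

    pick <- sample.int(length(allPos), n, replace = TRUE, prob = allW)
    dyad <- allPos[pick]
    chrom <- allChrom[pick]

    m <- params@fragmentLengthMean
    s <- params@fragmentLengthSd
    u <- stats::runif(n, stats::pnorm(80, m, s), stats::pnorm(220, m, s))
    len <- pmin(pmax(as.integer(round(stats::qnorm(u, m, s))), 80L), 220L)

    start <- dyad - (len - 1L) %/% 2L
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start, width = len),
        seqlengths = stats::setNames(width(genome), names(genome)))
    S4Vectors::mcols(gr)$mapq <- rep(60L, n)
    S4Vectors::mcols(gr)$mapq_unique <- rep(TRUE, n)
    GenomicRanges::sort(gr)
}

#' Run a full simulation: genome, truth, and fragments for every line
#'
#' @param params a [SimParams-class].
#' @return list with \code{genome}, \code{truth}, and \code{fragments}
#'   (named list of [GenomicRanges::GRanges-class], one per line).
#' @export
simulateDataset <- function(params) {
    sim <- simulateGenome(params)
    frags <- lapply(params@lines, function(ln)
        sampleFragments(sim$genome, sim$truth, ln,
                        params@nFragmentsPerLine, seed = params@seed))
    names(frags) <- params@lines
    c(sim, list(fragments = frags))
}

#' Write simulation outputs to disk
#'
#' Emits the genome as FASTA, gene models as GFF3, expression as TSV
#' (exon read counts at a nominal library size of 1e6, invertible by
#' [computeFpkm()]), fragments as BEDPE (one file per line), and the
#' ground truth as TSV + YAML parameter file.
#'
#' @param sim result of [simulateDataset()] (or [simulateGenome()], in
#'   which case no fragment files are written).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- sim$truth
    params <- truth@params
    paths <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "genes.gff3"),
               expression = file.path(dir, "expression.tsv"),
               motifs = file.path(dir, "truth_motifs.tsv"),
               multipliers = file.path(dir, "truth_multipliers.tsv"),
               params = file.path(dir, "params.yaml"))
    Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
    exportGeneModels(truth, paths[["annotation"]])

    g <- truth@genes
    exonLen <- vapply(split(truth@exons$end - truth@exons$start + 1L,
                            truth@exons$gene_id), sum, numeric(1))
    exonLen <- exonLen[g$gene_id]
    counts <- round(g$expression * (exonLen / 1000) * (1e6 / 1e6))
    utils::write.table(
        data.frame(transcript_id = g$gene_id, exon_read_count = counts,
                   transcript_length = exonLen),
        paths[["expression"]], sep = "\t", quote = FALSE, row.names = FALSE)

    mp <- truth@motifPositions
    mp$start0 <- mp$start - 1L
    utils::write.table(mp[, c("chrom", "start0", "heptamer")],
                       paths[["motifs"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lm <- do.call(rbind, lapply(names(truth@lineMultipliers), function(ln) {
        v <- truth@lineMultipliers[[ln]]
        if (!length(v)) return(NULL)
        data.frame(line = ln, heptamer = names(v), multiplier = unname(v))
    }))
    if (is.null(lm))
        lm <- data.frame(line = character(0), heptamer = character(0),
                         multiplier = numeric(0))
    utils::write.table(lm, paths[["multipliers"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(simParamsToList(params), paths[["params"]])

    if (!is.null(sim$fragments)) {
        for (ln in names(sim$fragments)) {
            p <- file.path(dir, sprintf("fragments_%s.bedpe", ln))
            writeFragmentsBedpe(sim$fragments[[ln]], p)
            paths[ln] <- p
        }
    }
    invisible(paths)
}

simParamsToList <- function(params) {
    list(genomeLength = params@genomeLength,
         nChromosomes = params@nChromosomes,
         gcContent = params@gcContent,
         nGenes = params@nGenes,
         nFragmentsPerLine = params@nFragmentsPerLine,
         fragmentLengthMean = params@fragmentLengthMean,
         fragmentLengthSd = params@fragmentLengthSd,
         periodicityWeight = params@periodicityWeight,
         polyAPenalty = params@polyAPenalty,
         plantedMotifs = lapply(params@plantedMotifs, as.list),
         motifCopies = params@motifCopies,
         occupancyLoci = lapply(params@occupancyLoci, function(l) {
             l$multipliers <- as.list(l$multipliers)
             l
         }),
         ndrWidth = params@ndrWidth,
         ndrBarrier = params@ndrBarrier,
         phasingAmplitude = params@phasingAmplitude,
         phasingDecay = params@phasingDecay,
         nucleosomeSpacing = params@nucleosomeSpacing,
         plusOneOffset = params@plusOneOffset,
         expressionLevels = as.list(params@expressionLevels),
         lines = as.list(params@lines),
         invitroLines = as.list(params@invitroLines),
         seed = params@seed)
}

#' Read simulation parameters from a YAML config
#'
#' @param path YAML file written by [writeSimulation()] or hand-authored.
#' @return a [SimParams-class].
#' @export
readSimParams <- function(path) {
    x <- yaml::read_yaml(path)
    x$plantedMotifs <- lapply(x$plantedMotifs, unlist)
    x$occupancyLoci <- lapply(x$occupancyLoci, function(l) {
        l$multipliers <- unlist(l$multipliers)
        l
    })
    x$expressionLevels <- as.numeric(unlist(x$expressionLevels))
    x$lines <- unlist(x$lines)
    x$invitroLines <- unlist(x$invitroLines)
    do.call(SimParams, x)
}

# GFF3 export of the truth's gene models (gene/mRNA/exon hierarchy)
exportGeneModels <- function(truth, path) {
    g <- truth@genes
    e <- truth@exons
    rows <- list()
    grGene <- GenomicRanges::GRanges(g$chrom,
                                     IRanges::IRanges(g$start, g$end),
                                     strand = g$strand)
    S4Vectors::mcols(grGene)$type <- "gene"
    S4Vectors::mcols(grGene)$ID <- g$gene_id
    S4Vectors::mcols(grGene)$Parent <- S4Vectors::unname(
        IRanges::CharacterList(rep(list(character(0)), nrow(g))))
    grRna <- grGene
    S4Vectors::mcols(grRna)$type <- "mRNA"
    S4Vectors::mcols(grRna)$ID <- paste0(g$gene_id, ".t1")
    S4Vectors::mcols(grRna)$Parent <- IRanges::CharacterList(as.list(g$gene_id))
    grEx <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                   strand = g$strand[match(e$gene_id, g$gene_id)])
    S4Vectors::mcols(grEx)$type <- "exon"
    S4Vectors::mcols(grEx)$ID <- NA_character_
    S4Vectors::mcols(grEx)$Parent <-
        IRanges::CharacterList(as.list(paste0(e$gene_id, ".t1")))
    all <- c(grGene, grRna, grEx)
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reconstructs the gene/exon tables used by [buildPartition()] and
#' [aggregateTss()] from a GFF3 annotation with gene and exon features.
#'
#' @param path GFF3 file.
#' @return list with data.frames \code{genes} (gene_id, chrom, start, end,
#'   strand, tss) and \code{exons} (gene_id, chrom, start, end).
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    ty <- as.character(gr$type)
    gg <- gr[ty == "gene"]
    rna <- gr[ty == "mRNA"]
    ex <- gr[ty == "exon"]
    genes <- data.frame(
        gene_id = gg$ID,
        chrom = as.character(GenomicRanges::seqnames(gg)),
        start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
        strand = as.character(GenomicRanges::strand(gg)),
        stringsAsFactors = FALSE)
    genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
    rna2gene <- stats::setNames(unlist(rna$Parent), rna$ID)
    exparent <- unlist(ex$Parent)
    exGene <- ifelse(exparent %in% names(rna2gene),
                     rna2gene[exparent], exparent)
    exons <- data.frame(
        gene_id = unname(exGene),
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
        stringsAsFactors = FALSE)
    list(genes = genes, exons = exons)
}
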