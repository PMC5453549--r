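#' @import methods
#' @importFrom S4Vectors isSingleNumber isSingleString
NULL

#' Simulation parameters for the synthetic MNase-seq generator
#'
#' An S4 container for all tunable parameters of the synthetic-data module.
#' The generator emulates mononucleosome MNase-seq libraries: fragments with
#' lengths centred near 147 bp, dyads placed by a sequence-dependent energy
#' (phased A/T dinucleotides at 10-bp period, poly(dA:dT) exclusion), a
#' promoter architecture (NDR plus phased downstream array scaling with
#' expression) for in vivo lines, and per-line occupancy multipliers at
#' planted heptamer motifs.
#'
#' @slot genomeLength total genome length in bp (split across chromosomes).
#' @slot nChromosomes number of chromosomes.
#' @slot gcContent target G+C fraction in [0,1].
#' @slot nGenes number of gene models to place.
#' @slot nFragmentsPerLine number of fragments sampled per dataset.
#' @slot fragmentLengthMean,fragmentLengthSd truncated-normal fragment length
#'   model on [80, 220] bp; defaults produce lengths both inside and outside
#'   the 101-191 bp retention band so the size filter is exercised.
#' @slot periodicityWeight energy coefficient of the phased A/T dinucleotide
#'   score (dimensionless; larger = stronger rotational positioning).
#' @slot polyAPenalty energy penalty per footprint base inside a poly(dA:dT)
#'   run of length >= 5.
#' @slot plantedMotifs named list: heptamer -> named numeric vector of
#'   per-line occupancy multipliers (lines absent from the vector get 1).
#' @slot motifCopies number of genomic copies planted per motif.
#' @slot occupancyLoci list of region-level occupancy modifiers, each a
#'   list with \code{chrom}, \code{start}, \code{end} (1-based, inclusive)
#'   and \code{multipliers} (named numeric per line); dyads inside the
#'   region get \code{-log(multiplier)} added to their energy.
#' @slot ndrWidth width in bp of the nucleosome-depleted region upstream of
#'   each TSS.
#' @slot ndrBarrier energy barrier height over the NDR.
#' @slot phasingAmplitude coefficient of the phased downstream bonus; the
#'   per-gene amplitude is \code{phasingAmplitude * pmax(log10(fpkm), 0)}.
#' @slot phasingDecay distance scale (bp) of the exponential decay of the
#'   downstream array bonus, so positioning strength fades with distance
#'   from the TSS.
#' @slot nucleosomeSpacing nucleosome repeat length of the simulated
#'   downstream array in bp.
#' @slot plusOneOffset dyad position of the +1 nucleosome relative to the
#'   TSS in bp.
#' @slot expressionLevels optional per-gene FPKM-like positive reals; when
#'   empty, levels are drawn log-normally from the seed.
#' @slot lines dataset labels to simulate.
#' @slot invitroLines subset of \code{lines} treated as reconstituted
#'   chromatin: no promoter architecture term (sequence-intrinsic placement
#'   only).
#' @slot seed integer seed; fully determines all outputs.
#'
#' @seealso [SimParams()] for the user constructor.
#' @export
setClass("SimParams", representation(
    genomeLength = "numeric",
    nChromosomes = "integer",
    gcContent = "numeric",
    nGenes = "integer",
    nFragmentsPerLine = "numeric",
    fragmentLengthMean = "numeric",
    fragmentLengthSd = "numeric",
    periodicityWeight = "numeric",
    polyAPenalty = "numeric",
    plantedMotifs = "list",
    motifCopies = "integer",
    occupancyLoci = "list",
    ndrWidth = "integer",
    ndrBarrier = "numeric",
    phasingAmplitude = "numeric",
    phasingDecay = "numeric",
    nucleosomeSpacing = "numeric",
    plusOneOffset = "integer",
    expressionLevels = "numeric",
    lines = "character",
    invitroLines = "character",
    seed = "integer"
))

setValidity("SimParams", function(object) {
    msg <- character(0)
    if (object@gcContent < 0 || object@gcContent > 1)
        msg <- c(msg, "gcContent must be in [0, 1]")
    if (object@genomeLength < 1000)
        msg <- c(msg, "genomeLength must be >= 1000 bp")
    if (object@nChromosomes < 1L)
        msg <- c(msg, "nChromosomes must be >= 1")
    if (object@fragmentLengthSd <= 0)
        msg <- c(msg, "fragmentLengthSd must be > 0")
    for (m in names(object@plantedMotifs)) {
        mult <- object@plantedMotifs[[m]]
        if (nchar(m) != 7L || grepl("[^ACGT]", m))
            msg <- c(msg, sprintf("planted motif '%s' is not an ACGT heptamer", m))
        if (any(mult <= 0))
            msg <- c(msg, sprintf("multipliers for motif '%s' must be > 0", m))
        if (!all(names(mult) %in% object@lines))
            msg <- c(msg, sprintf("multiplier lines for '%s' not all in 'lines'", m))
    }
    if (length(object@expressionLevels) &&
        length(object@expressionLevels) != object@nGenes)
        msg <- c(msg, "expressionLevels must have length nGenes (or 0)")
    if (any(object@expressionLevels < 0))
        msg <- c(msg, "expressionLevels must be >= 0")
    if (!all(object@invitroLines %in% object@lines))
        msg <- c(msg, "invitroLines must be a subset of lines")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic simulation
#'
#' Records everything the generator decided: planted motif positions,
#' per-line occupancy multipliers, gene models with expression, and the
#' generating [SimParams]. Every planted position is guaranteed to carry its
#' heptamer literally in the emitted genome.
#'
#' @slot motifPositions data.frame with columns \code{chrom}, \code{start}
#'   (1-based first base of the heptamer), \code{heptamer}.
#' @slot lineMultipliers named list: line -> named numeric vector
#'   (heptamer -> multiplier), complete over all lines and planted motifs.
#' @slot genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{tss}, \code{expression}.
#' @slot exons data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @slot params the generating [SimParams].
#' @export
setClass("SyntheticTruth", representation(
    motifPositions = "data.frame",
    lineMultipliers = "list",
    genes = "data.frame",
    exons = "data.frame",
    params = "SimParams"
))

#' Per-base-pair nucleosome dyad midpoint track
#'
#' Integer counts of fragment midpoints (dyad estimates) at every base of
#' every chromosome, together with the number of retained fragments the
#' track was built from. The invariant \code{sum(counts) == totalFragments}
#' holds by construction.
#'
#' @slot counts named list of integer vectors, one per chromosome, each of
#'   length equal to the chromosome length.
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot totalFragments number of retained fragments contributing midpoints.
#' @slot sourceLabel dataset identifier.
#' @export
setClass("MidpointTrack", representation(
    counts = "list",
    seqlengths = "integer",
    totalFragments = "numeric",
    sourceLabel = "character"
))

setValidity("MidpointTrack", function(object) {
    msg <- character(0)
    if (!identical(names(object@counts), names(object@seqlengths)))
        msg <- c(msg, "counts and seqlengths must share chromosome names")
    lens <- vapply(object@counts, length, integer(1))
    if (length(lens) && any(lens != unname(object@seqlengths)))
        msg <- c(msg, "count vector lengths must equal seqlengths")
    tot <- sum(vapply(object@counts, function(x) sum(as.numeric(x)), numeric(1)))
    if (tot != object@totalFragments)
        msg <- c(msg, "sum of counts must equal totalFragments")
    if (any(vapply(object@counts, function(x) any(x < 0), logical(1))))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Per-k-mer occupancy rate table
#'
#' For one dataset, the genomic occurrence count of every k-mer (all 4^k,
#' forward-strand literal overlapping matches) and its occupancy rate: the
#' mean fragment coverage depth over the 200-bp region centred on each
#' occurrence, averaged over occurrences and normalized per million
#' retained fragments. Rates are \code{NA} for k-mers with no usable
#' occurrence.
#'
#' @slot label dataset identifier.
#' @slot k word length.
#' @slot occurrences named integer vector of length 4^k.
#' @slot rates named numeric vector of length 4^k.
#' @slot totalFragments fragment count used for per-million normalization.
#' @export
setClass("KmerRateTable", representation(
    label = "character",
    k = "integer",
    occurrences = "integer",
    rates = "numeric",
    totalFragments = "numeric"
))

setValidity("KmerRateTable", function(object) {
    msg <- character(0)
    nk <- 4L^object@k
    if (length(object@occurrences) != nk || length(object@rates) != nk)
        msg <- c(msg, sprintf("occurrences and rates must have length 4^k = %d", nk))
    if (any(object@occurrences < 0))
        msg <- c(msg, "occurrence counts must be >= 0")
    if (any(!is.na(object@rates) & object@rates < 0))
        msg <- c(msg, "rates must be >= 0 where defined")
    if (length(msg)) msg else TRUE
})
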