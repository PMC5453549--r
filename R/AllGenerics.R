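#' @rdname MidpointTrack-class
#' @param x a \code{MidpointTrack}
#' @export
setGeneric("midpointCounts", function(x) standardGeneric("midpointCounts"))

#' @rdname MidpointTrack-class
#' @export
setGeneric("totalFragments", function(x) standardGeneric("totalFragments"))

#' @rdname MidpointTrack-class
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname SyntheticTruth-class
#' @param x a \code{SyntheticTruth}
#' @export
setGeneric("motifPositions", function(x) standardGeneric("motifPositions"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("lineMultipliers", function(x) standardGeneric("lineMultipliers"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("exonModels", function(x) standardGeneric("exonModels"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname KmerRateTable-class
#' @param x a \code{KmerRateTable}
#' @export
setGeneric("kmerRates", function(x) standardGeneric("kmerRates"))

#' @rdname KmerRateTable-class
#' @export
setGeneric("kmerOccurrences", function(x) standardGeneric("kmerOccurrences"))

#' @rdname KmerRateTable-class
#' @export
setGeneric("datasetLabel", function(x) standardGeneric("datasetLabel"))

setMethod("midpointCounts", "MidpointTrack", function(x) x@counts)
setMethod("totalFragments", "MidpointTrack", function(x) x@totalFragments)
setMethod("sourceLabel", "MidpointTrack", function(x) x@sourceLabel)
setMethod("totalFragments", "KmerRateTable", function(x) x@totalFragments)

setMethod("motifPositions", "SyntheticTruth", function(x) x@motifPositions)
setMethod("lineMultipliers", "SyntheticTruth", function(x) x@lineMultipliers)
setMethod("geneModels", "SyntheticTruth", function(x) x@genes)
setMethod("exonModels", "SyntheticTruth", function(x) x@exons)
setMethod("simParams", "SyntheticTruth", function(x) x@params)

setMethod("kmerRates", "KmerRateTable", function(x) x@rates)
setMethod("kmerOccurrences", "KmerRateTable", function(x) x@occurrences)
setMethod("datasetLabel", "KmerRateTable", function(x) x@label)

#' @describeIn MidpointTrack-class chromosome lengths of the track
#' @importFrom GenomeInfoDb seqlengths
#' @export
setMethod("seqlengths", "MidpointTrack", function(x) x@seqlengths)

setMethod("show", "MidpointTrack", function(object) {
    cat("MidpointTrack '", object@sourceLabel, "'\n", sep = "")
    cat("  ", length(object@counts), " chromosome(s), ",
        sum(as.numeric(object@seqlengths)), " bp\n", sep = "")
    cat("  ", format(object@totalFragments, big.mark = ","),
        " fragment midpoints\n", sep = "")
})

setMethod("show", "SimParams", function(object) {
    cat("SimParams: ", object@genomeLength, " bp / ", object@nChromosomes,
        " chromosome(s), GC ", object@gcContent, ", ", object@nGenes,
        " genes, ", object@nFragmentsPerLine, " fragments per line\n", sep = "")
    cat("  lines: ", paste(object@lines, collapse = ", "), "\n", sep = "")
    if (length(object@plantedMotifs))
        cat("  planted motifs: ",
            paste(names(object@plantedMotifs), collapse = ", "), "\n", sep = "")
    cat("  seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: ", nrow(object@genes), " genes, ",
        nrow(object@motifPositions), " planted motif positions (",
        length(unique(object@motifPositions$heptamer)), " motifs)\n", sep = "")
})

setMethod("show", "KmerRateTable", function(object) {
    def <- sum(!is.na(object@rates))
    cat("KmerRateTable '", object@label, "': ", 4L^object@k, " ",
        object@k, "-mers (", def, " with defined rates), ",
        format(object@totalFragments, big.mark = ","), " fragments\n", sep = "")
})
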