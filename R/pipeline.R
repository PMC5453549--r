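# End-to-end orchestration: config, logging, and the full analysis run.

#' Build a run configuration
#'
#' All thresholds default to the published values of the analyses this
#' package implements: 101-191 bp fragment retention, MAPQ 20, promoter =
#' TSS +/- 500 bp, 200-bp windows with fold > 2 and FDR < 0.01, pentamer
#' (k = 5) depletion statistics, heptamer (k = 7) screen with top-20
#' outliers, TSS profiles over +/- 1 kb smoothed with a 20-bp sliding
#' window. Every number used by [runPipeline()] appears in the serialized
#' config.
#'
#' @param genome path to the genome FASTA (or a DNAStringSet).
#' @param annotation path to the gene annotation GFF3.
#' @param fragments named list: dataset label -> fragment file (BEDPE/BED/
#'   BAM) or GRanges.
#' @param expression path to the expression TSV (transcript_id,
#'   exon_read_count, transcript_length) or a data.frame; optional.
#' @param invitroLabel dataset treated as reconstituted chromatin (left
#'   out of the mean-of-lines table); NA if none.
#' @param referenceLabel reference dataset for window comparisons
#'   (default: first dataset).
#' @param outdir output directory.
#' @param minLength,maxLength,mapqThreshold fragment retention filter.
#' @param promoterFlank,windowSize,foldThreshold,fdrThreshold,pentamerK,heptamerK,topN,tssFlank,tssSmooth,profileFlank
#'   analysis thresholds (see module functions).
#' @param librarySize RNA-seq library size for FPKM (default 1e6).
#' @param seed integer seed recorded with the run.
#' @return a named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(genome, annotation, fragments, expression = NULL,
                      invitroLabel = "invitro", referenceLabel = NULL,
                      outdir = "nucleoscope_out",
                      minLength = 101L, maxLength = 191L,
                      mapqThreshold = 20L, promoterFlank = 500L,
                      windowSize = 200L, foldThreshold = 2,
                      fdrThreshold = 0.01, pentamerK = 5L, heptamerK = 7L,
                      topN = 20L, tssFlank = 1000L, tssSmooth = 20L,
                      profileFlank = 200L, librarySize = 1e6, seed = 1L) {
    if (is.null(referenceLabel)) referenceLabel <- names(fragments)[1]
    cfg <- list(genome = genome, annotation = annotation,
                fragments = fragments, expression = expression,
                invitroLabel = invitroLabel,
                referenceLabel = referenceLabel, outdir = outdir,
                minLength = as.integer(minLength),
                maxLength = as.integer(maxLength),
                mapqThreshold = as.integer(mapqThreshold),
                promoterFlank = as.integer(promoterFlank),
                windowSize = as.integer(windowSize),
                foldThreshold = foldThreshold,
                fdrThreshold = fdrThreshold,
                pentamerK = as.integer(pentamerK),
                heptamerK = as.integer(heptamerK), topN = as.integer(topN),
                tssFlank = as.integer(tssFlank),
                tssSmooth = as.integer(tssSmooth),
                profileFlank = as.integer(profileFlank),
                librarySize = librarySize, seed = as.integer(seed))
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [runConfig()].
#' @return a \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    x <- yaml::read_yaml(path)
    do.call(runConfig, x)
}

validateConfig <- function(cfg) {
    if (cfg$minLength > cfg$maxLength)
        stopf("invalid config: minLength (%d) > maxLength (%d)",
              cfg$minLength, cfg$maxLength)
    if (!length(cfg$fragments) || is.null(names(cfg$fragments)))
        stopf("invalid config: 'fragments' must be a named list")
    if (!cfg$referenceLabel %in% names(cfg$fragments))
        stopf("invalid config: referenceLabel '%s' not among datasets",
              cfg$referenceLabel)
    if (cfg$fdrThreshold <= 0 || cfg$fdrThreshold >= 1)
        stopf("invalid config: fdrThreshold must be in (0,1)")
    invisible(TRUE)
}

# serialize config (paths only, not in-memory objects) for provenance
configForSerialization <- function(cfg) {
    ser <- cfg
    if (!is.character(ser$genome)) ser$genome <- "<in-memory>"
    if (!is.null(ser$annotation) && !is.character(ser$annotation))
        ser$annotation <- "<in-memory>"
    if (!is.null(ser$expression) && !is.character(ser$expression))
        ser$expression <- "<in-memory>"
    ser$fragments <- lapply(ser$fragments, function(f)
        if (is.character(f)) f else "<in-memory>")
    unclass(ser)
}

pipelineLogger <- function(path) {
    con <- file(path, "w")
    list(log = function(...) {
        msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                       sprintf(...))
        writeLines(msg, con)
        message(msg)
    }, close = function() close(con))
}

writeTsv <- function(df, path, header = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (h in header) writeLines(paste0("# ", h), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full comparative nucleosome-organization pipeline
#'
#' Executes all modules in dependency order: fragment loading and
#' retention filtering, midpoint tracks, phasogram and pentamer depletion
#' statistics, expression-stratified TSS profiles, region densities,
#' differential 200-bp windows against the reference dataset, and the
#' heptamer residual-outlier screen. Every table is written under
#' \code{cfg$outdir} with a provenance header (config hash, package
#' version); the serialized config and a stage log accompany the outputs.
#'
#' @param cfg a \code{"RunConfig"} from [runConfig()] or
#'   [readRunConfig()].
#' @return invisibly, a list with the in-memory results
#'   (\code{tracks}, \code{phasograms}, \code{enrichments},
#'   \code{tssProfiles}, \code{regionDensities}, \code{windowComparisons},
#'   \code{outlierReport}, \code{fragmentStats}, \code{outdir}).
#' @export
runPipeline <- function(cfg) {
    validateConfig(cfg)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    lg <- pipelineLogger(file.path(cfg$outdir, "pipeline.log"))
    on.exit(lg$close())

    ser <- configForSerialization(cfg)
    cfgPath <- file.path(cfg$outdir, "config.yaml")
    yaml::write_yaml(ser, cfgPath)
    # hash the analysis-relevant config (not the output location) so reruns
    # of one configuration are byte-identical wherever they are written
    hashable <- ser
    hashable$outdir <- NULL
    tmp <- tempfile()
    yaml::write_yaml(hashable, tmp)
    cfgHash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    prov <- c(sprintf("NucleoScope %s",
                      as.character(utils::packageVersion("NucleoScope"))),
              sprintf("config md5 %s", cfgHash))

    stage <- function(name, expr) {
        lg$log("stage %s", name)
        tryCatch(expr, error = function(e)
            stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    }

    genome <- stage("genome", {
        if (is.character(cfg$genome)) Biostrings::readDNAStringSet(cfg$genome)
        else cfg$genome
    })
    names(genome) <- sub("\\s.*$", "", names(genome))
    seqlens <- stats::setNames(Biostrings::width(genome), names(genome))

    ann <- stage("annotation", {
        if (is.character(cfg$annotation)) readGeneModels(cfg$annotation)
        else cfg$annotation
    })

    tracks <- list()
    fragStats <- list()
    covs <- list()
    for (ds in names(cfg$fragments)) {
        frg <- stage(paste0("load:", ds), {
            f <- cfg$fragments[[ds]]
            if (is.character(f))
                loadFragments(f, mapqThreshold = cfg$mapqThreshold,
                              seqlengths = seqlens)
            else f
        })
        kept <- filterFragments(frg, cfg$minLength, cfg$maxLength)
        lg$log("%s: %d fragments in, %d retained (%.1f%%)", ds,
               length(frg), length(kept), 100 * length(kept) /
                   max(1L, length(frg)))
        fragStats[[ds]] <- data.frame(dataset = ds, loaded = length(frg),
                                      retained = length(kept))
        tracks[[ds]] <- buildMidpointTrack(kept, seqlens, label = ds)
        covs[[ds]] <- coverageTrack(kept, seqlens)
        writeBedGraph(tracks[[ds]],
                      file.path(cfg$outdir, sprintf("midpoints_%s.bedgraph", ds)))
    }
    writeTsv(do.call(rbind, fragStats),
             file.path(cfg$outdir, "fragment_stats.tsv"), prov)

    phasograms <- list()
    enrichments <- list()
    for (ds in names(tracks)) {
        ph <- stage(paste0("phasogram:", ds),
                    computePhasogram(tracks[[ds]], genome))
        phasograms[[ds]] <- ph
        writeTsv(data.frame(offset = ph$offsets, ww_freq = ph$ww_freq,
                            ss_freq = ph$ss_freq),
                 file.path(cfg$outdir, sprintf("phasogram_%s.tsv", ds)), prov)
        en <- stage(paste0("pentamers:", ds),
                    kmerEnrichment(tracks[[ds]], genome, k = cfg$pentamerK))
        enrichments[[ds]] <- en
        writeTsv(data.frame(kmer = names(en$P), P = en$P,
                            P_nucleosome = en$P_nucleosome,
                            log2_ratio = en$log2_ratio),
                 file.path(cfg$outdir, sprintf("kmer_enrichment_%s.tsv", ds)),
                 prov)
    }

    tssTable <- data.frame(transcript_id = ann$genes$gene_id,
                           chrom = ann$genes$chrom, tss = ann$genes$tss,
                           strand = ann$genes$strand,
                           stringsAsFactors = FALSE)
    tssProfiles <- NULL
    if (!is.null(cfg$expression)) {
        expr <- stage("expression", {
            e <- cfg$expression
            if (is.character(e))
                utils::read.table(e, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
            else e
        })
        fpkmTab <- computeFpkm(expr$exon_read_count, expr$transcript_length,
                               cfg$librarySize, ids = expr$transcript_id)
        tssProfiles <- lapply(names(tracks), function(ds)
            stage(paste0("tss:", ds),
                  stratifiedTssProfiles(tracks[[ds]], tssTable, fpkmTab,
                                        flank = cfg$tssFlank,
                                        smooth = cfg$tssSmooth)))
        names(tssProfiles) <- names(tracks)
        for (ds in names(tssProfiles))
            for (s in names(tssProfiles[[ds]])) {
                pr <- tssProfiles[[ds]][[s]]
                writeTsv(data.frame(offset = pr$offsets, rate = pr$rate,
                                    rate_per_million = pr$rate_per_million),
                         file.path(cfg$outdir,
                                   sprintf("tss_profile_%s_%s.tsv", ds, s)),
                         c(prov, sprintf("stratum %s, n_tss %d", s, pr$n_tss)))
            }
    }

    partition <- stage("partition",
                       buildPartition(ann$genes, ann$exons, seqlens,
                                      promoterFlank = cfg$promoterFlank))
    writePartitionBed(partition, file.path(cfg$outdir, "partition.bed"))
    regionDensities <- do.call(rbind, lapply(names(tracks), function(ds) {
        d <- stage(paste0("regions:", ds), regionDensity(tracks[[ds]], partition))
        d$dataset <- ds
        d
    }))
    writeTsv(regionDensities, file.path(cfg$outdir, "region_density.tsv"),
             prov)

    ref <- cfg$referenceLabel
    refWin <- windowCounts(tracks[[ref]], cfg$windowSize)
    windowComparisons <- list()
    for (ds in setdiff(names(tracks), ref)) {
        wc <- stage(paste0("windows:", ds), {
            win <- windowCounts(tracks[[ds]], cfg$windowSize)
            compareWindows(win, refWin,
                           totalA = tracks[[ds]]@totalFragments,
                           totalB = tracks[[ref]]@totalFragments,
                           fold = cfg$foldThreshold, fdr = cfg$fdrThreshold)
        })
        windowComparisons[[ds]] <- wc
        writeTsv(wc$windows,
                 file.path(cfg$outdir, sprintf("windows_%s_vs_%s.tsv", ds, ref)),
                 c(prov, sprintf("pearson_r %.4f, n_called %d of %d tested",
                                 wc$pearson_r, wc$n_called, wc$n_tested)))
        writeCalledWindowsBed(wc, file.path(
            cfg$outdir, sprintf("called_windows_%s_vs_%s.bed", ds, ref)))
    }

    occ <- stage("heptamer occurrences",
                 heptamerOccurrences(genome, k = cfg$heptamerK))
    rateTables <- lapply(names(covs), function(ds)
        stage(paste0("heptamer rates:", ds),
              heptamerRates(covs[[ds]], occ, label = ds)))
    names(rateTables) <- names(covs)
    invitro <- if (!is.na(cfg$invitroLabel) &&
                   cfg$invitroLabel %in% names(rateTables))
        rateTables[[cfg$invitroLabel]] else NULL
    lines <- rateTables[setdiff(names(rateTables),
                                if (is.null(invitro)) character(0)
                                else cfg$invitroLabel)]
    outlierReport <- stage("heptamer screen",
                           runAllComparisons(lines, invitro, topN = cfg$topN))
    writeTsv(outlierReport$union,
             file.path(cfg$outdir, "heptamer_outlier_union.tsv"), prov)
    rm <- outlierReport$residualMatrix
    writeTsv(data.frame(heptamer = rownames(rm), rm, check.names = FALSE),
             file.path(cfg$outdir, "heptamer_residual_matrix.tsv"), prov)
    rateDf <- data.frame(heptamer = names(rateTables[[1]]@rates))
    for (ds in names(rateTables)) rateDf[[ds]] <- rateTables[[ds]]@rates
    rateDf$occurrences <- rateTables[[1]]@occurrences
    writeTsv(rateDf, file.path(cfg$outdir, "heptamer_rates.tsv"), prov)

    lg$log("pipeline complete: %s", cfg$outdir)
    invisible(list(tracks = tracks, phasograms = phasograms,
                   enrichments = enrichments, tssProfiles = tssProfiles,
                   partition = partition, regionDensities = regionDensities,
                   windowComparisons = windowComparisons,
                   rateTables = rateTables, outlierReport = outlierReport,
                   fragmentStats = do.call(rbind, fragStats),
                   outdir = cfg$outdir))
}
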