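Package: NucleoScope
Title: Comparative MNase-Seq Nucleosome Organization Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of nucleosome organization from
    paired-end MNase-seq fragment data across cell lines and in vitro
    reconstituted chromatin. Builds dyad midpoint tracks from size-selected
    fragments, computes dinucleotide periodicity around dyads and k-mer
    genome-versus-nucleosome depletion statistics, expression-stratified
    aggregate profiles around transcription start sites, midpoint densities
    by functional genomic region, differential occupancy calls over
    non-overlapping 200-bp windows, and a heptamer residual-outlier screen
    that identifies short sequences with dataset-specific occupancy.
    Includes a sequence-dependent nucleosome placement simulator (phased
    A/T dinucleotide energy, poly(dA:dT) exclusion, promoter architecture,
    planted motif perturbations) for generating fully specified synthetic
    datasets with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, NucleosomePositioning, Sequencing, Coverage
RoxygenNote: 7.3.3
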