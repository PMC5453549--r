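---
title: "Comparative nucleosome organization from MNase-seq fragments"
author: "NucleoScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative nucleosome organization from MNase-seq fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

NucleoScope implements a comparative analysis of nucleosome organization
from paired-end MNase-seq data across multiple cell lines and in vitro
reconstituted chromatin. The analytical chain is: size-selected fragment
retention, dyad (midpoint) tracks, dinucleotide periodicity around dyads,
k-mer genome-versus-nucleosome depletion statistics, expression-stratified
aggregate profiles around transcription start sites (TSSs), midpoint
density by functional region, differential occupancy over fixed 200-bp
windows, and a heptamer residual-outlier screen that flags short sequences
whose occupancy differs between datasets. A sequence-dependent placement
simulator generates fully specified synthetic datasets with ground truth,
so every statistic can be exercised against known signals.

# Fragment processing conventions

MNase digestion of chromatin releases mononucleosome-protected fragments
of roughly 147 bp. The retention filter keeps uniquely mapped pairs with
fragment length in **101-191 bp inclusive** — a symmetric 45-bp margin
around the canonical core-particle length. "Unique" is interpreted as a
mapping-quality threshold (default MAPQ >= 20), not positional
deduplication: collapsing identical coordinates would distort occupancy
quantitation, so deduplication exists only as an off-by-default flag.

The nucleosome dyad is estimated as the fragment midpoint,
`start0 + floor((length - 1)/2)` in 0-based coordinates; even-length
fragments break the tie toward the lower coordinate, which is the unique
deterministic choice consistent with the simulator's inverse rule
(`start = dyad - floor((len - 1)/2)`), so midpoints round-trip exactly
through simulation and analysis. Internally the package uses Bioconductor
containers (GRanges, 1-based closed intervals); everything written to disk
in BED dialects (bedGraph, BED, BEDPE) is 0-based half-open.

# Sequence bias statistics

**Phasogram.** For every offset in −73..+73 from each midpoint the
forward-strand dinucleotide starting at that position is classified as
A/T (AA, AT, TA, TT) or C/G (CC, CG, GC, GG), weighted by midpoint
multiplicity. Both classes are closed under reverse complementation, so
the choice of strand is immaterial — a property the test suite verifies
by recomputing on the reverse-complemented genome with mirrored midpoints.
Windows touching a chromosome end or an ambiguous base are skipped whole
(partial windows would bias the tails). The dominant period is estimated
from the autocorrelation of the detrended A/T-class signal over offsets
−60..60; rotational positioning appears as a peak at ~10 bp.

**k-mer depletion.** `log2(P / P_nucleosome)` compares each k-mer's
genomic frequency with its frequency in the 147-bp windows centred on
midpoints (windows weighted by midpoint count). Positive values mean
depletion from nucleosomal DNA. For pentamers (k = 5, 1,024 words) the
distribution is summarized for the 32 A/T-only words, the 32 G/C-only
words, and the full set. k-mers are literal forward-strand words — no
reverse-complement collapsing — because the screen treats complementary
words as distinct entries. Words with zero frequency in either vector are
flagged undefined and excluded from distribution summaries rather than
imputed.

# TSS profiles and expression strata

Expression is quantified as FPKM, `count / (length/1000) / (library/1e6)`,
with `log10(FPKM)` as the working measure; zero-FPKM transcripts receive a
pseudocount of half the smallest nonzero FPKM, which keeps ranks unchanged
while making the strata well defined. Transcripts are ranked and split
bottom 25% / middle 50% / top 25% (stable order for ties; stratum sizes
within one of the exact fractions).

Aggregate profiles sum midpoint counts at strand-oriented offsets in
±1 kb around deduplicated TSS positions, divide by the TSS count, and
smooth with a 20-bp centred moving average truncated at the window ends
(no padding). Midpoints falling in the overlapping flanks of nearby TSSs
are counted once per TSS — the profile is a per-TSS average, not an
ownership assignment. Both the per-TSS rate and a per-million-normalized
variant are emitted; the per-TSS rate is the default y-axis.

# Regions, windows, and the differential caller

The genome is partitioned into promoter (TSS ± 500 bp), exon, intron and
intergenic labels with precedence promoter > exon > intron: the promoter
definition is explicit and symmetric around the TSS, so it wins overlaps,
and exon beats intron by construction. Midpoint density is reported per bp
of label per million fragments; raw counts and per-million-only values are
also emitted, since length normalization is required to compare labels of
unequal size.

For differential occupancy the genome is tiled with non-overlapping
200-bp windows from coordinate 0 (trailing partial windows are
length-adjusted and flagged). No specific test is canonical for
single-sample count comparisons here, so the caller uses a two-sided
conditional binomial test on the two counts given their sum (null success
probability = library-size ratio), Benjamini–Hochberg adjustment across
windows with nonzero total, and calls a window only when q < 0.01 **and**
the FPKM ratio (pseudocount 0.5 on both counts) exceeds 2. The test is
deliberately pluggable at the function boundary; the BH step is validated
against a sort-based oracle in the suite. Windows empty in both datasets
are untestable and excluded from testing but kept in tables.

# The heptamer screen

For each of the 16,384 heptamers, the occupancy rate is the mean fragment
coverage depth ("read depth" denotes coverage, not midpoints) over the
200-bp region centred on the heptamer's central base at every genomic
occurrence, averaged over occurrences and normalized per million
fragments. Occurrence-centred regions (not fixed genome tiles) are used;
occurrences whose region would be clipped by a chromosome end are
dropped. Each unordered pair of datasets — the individual lines, their
unweighted per-heptamer mean, and in vitro chromatin, 15 pairs for six
datasets — is compared by ordinary least squares of one rate vector on
the other on the linear scale (no transform is assumed), and the 20
heptamers with the largest absolute residuals are outliers, ties broken
lexicographically. The union over comparisons is reported with
per-comparison provenance, plus a residual matrix (each line versus the
mean of lines; in vitro versus the mean). Midpoint-density profiles
centred on any heptamer (±200 bp, or ±2 kb for long-range ordering) use
the same smoothing as TSS profiles.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is checked. Defaults describe one
study condition — a 200-kb chromosome at 43% GC (fly-like), 50 genes,
2×10^5 fragments per dataset, truncated-normal fragment lengths
(mean 147, sd 20 on [80, 220] bp, so the 101-191 retention filter is
genuinely exercised), four in vivo lines plus one in vitro line, and one
planted heptamer (AATAATA, 80 copies) with a 3-fold occupancy multiplier
in a single line.

Placement follows a Boltzmann model over dyad positions,
`P(dyad) ∝ exp(-E)`, with a dyad-registered energy in three
sequence-intrinsic terms:

* a phased A/T-dinucleotide term: the indicator of {AA, AT, TA, TT}
  dinucleotide starts across the 147-bp footprint correlated with a
  **zero-sum** period-10 cosine kernel, weighted by `periodicityWeight`.
  The kernel is centred to zero mean so uniform A/T content is not
  rewarded — only its 10-bp phasing relative to the dyad;
* a poly(dA:dT) exclusion term: `polyAPenalty` per footprint base inside
  an A or T homopolymer run of length >= 5;
* `-log(multiplier)` for footprints overlapping a planted motif (or an
  `occupancyLoci` region) in the sampled line.

In vivo lines additionally receive a promoter-architecture term: an
energy barrier over `[TSS - ndrWidth, TSS)` and a phased harmonic bonus
over the first kilobase downstream, period `nucleosomeSpacing` (175 bp)
anchored at the +1 dyad (+75 bp). Both scale with expression
(`pmax(log10 FPKM, 0)`; the barrier saturates at its full height by
FPKM = 100), and the bonus decays exponentially (`phasingDecay` = 120 bp)
so the +1 nucleosome is the dominant aggregate feature and downstream
positioning fades with distance — the qualitative promoter organization
of active genes. The in vitro line omits this term entirely: it reflects
sequence-intrinsic placement only, which is exactly what reconstituted
chromatin contributes to the comparison.

The energy coefficients are free parameters — nothing in the analysed
phenomenon fixes them quantitatively — and were chosen once, by scanning
for the regime that reproduces the canonical signal directions
(autocorrelation period 10 bp; AAAAA depleted; the A/T-only pentamer
class depleted relative to all pentamers; NDR + dominant +1 for highly
expressed genes with reduced contrast for weakly expressed ones) robustly
across seeds: `periodicityWeight = 0.05`, `polyAPenalty = 0.25`,
`ndrBarrier = 2`, `phasingAmplitude = 1.2`. At materially larger
periodicity weights the convexity of the Boltzmann map over-covers
A/T-rich sequence and inverts the pentamer-class ordering; the chosen
value keeps the rotational signal detectable without that artefact.

All randomness derives from one master seed through per-(stage, line)
derived streams, so outputs are byte-identical across reruns and
per-stage seeds can be varied independently (as the null-calibration
checks do).

**What the generator does not emulate:** sequencing error and base-call
quality, mappability structure and repeats, GC amplification bias,
MNase's own sequence preference, chromatin remodeler kinetics, and
replicate-to-replicate biological variability. Passing tests therefore
demonstrate that the statistics recover the signals they are defined to
measure under a clean generative model — not that real libraries are free
of these confounders.

# Numerical choices and degeneracies

* Even-length midpoints tie to the lower coordinate; documented above.
* Moving averages are truncated at window ends, never padded; for even
  widths the window extends `floor((w-1)/2)` left and `floor(w/2)` right.
* OLS residuals smaller than 1e-9 of the response scale are snapped to
  exact zero so the degenerate identical-table comparison resolves by the
  documented lexicographic tie rule instead of floating-point noise.
* Heptamers with zero usable occurrences carry `NA` rates and are
  excluded from regressions; comparisons require >= 3 shared heptamers.
* Fragment sampling restricts dyads to 110 bp from chromosome ends so the
  longest possible fragment (220 bp) always fits without clipping.
* `compareWindows` excludes windows with zero counts in both datasets
  from testing (they carry no information) but keeps them in the table.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data
generated at run time: a 50-kb simulation for unit tests and oracle
comparisons (brute-force nested-loop oracles are quadratic, so oracle
checks use 6-50 kb genomes and thinned midpoint sets), the 200-kb default
condition for signal-direction and recovery checks (20 seeded replicates
for the planted-heptamer screen), and a gene-rich 400-kb / 100-gene
condition for TSS-profile shape, where 50 genes would leave only ~12
high-expression TSSs and single sequence hotspots can dominate the
aggregate. These sizes are the package's own choices balancing
statistical resolution of each check against desk-scale runtimes.

# Known limitations

* The heptamer-rate regression is on linear rates; residual magnitudes
  are therefore not comparable across datasets with very different
  dynamic ranges, and no uncertainty is attached to the top-20 cut.
* The window caller models only sampling noise; without replicates,
  biological dispersion is indistinguishable from signal, as for any
  single-sample design.
* Forward-strand literal k-mer matching means palindromic and
  complementary words are separate rows; downstream interpretation should
  pair them when strandless conclusions are wanted.
* The conditional binomial test assumes independent fragments;
  MNase-seq duplicates and local correlations make the nominal FDR
  approximate on real data.
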