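# NucleoScope

Comparative analysis of nucleosome organization from paired-end MNase-seq
fragments, for chromatin biologists comparing cell types (or in vivo
chromatin against in vitro reconstitution). Micrococcal nuclease digestion
protects ~147 bp of DNA per nucleosome; sequencing the protected fragments
and mapping their midpoints (dyads) genome-wide turns "where are the
nucleosomes" into a counting problem. NucleoScope covers the full
analytical chain and ships a sequence-dependent placement simulator so the
whole chain can be validated against planted ground truth.

## What it computes

Starting from fragment alignments (BAM/BEDPE/BED), a genome FASTA and a
GFF3 annotation:

* **Retention + dyad tracks** — keep unique pairs with length in
  101–191 bp (inclusive); midpoint = `start + floor((len-1)/2)`.
* **Dinucleotide phasogram** — frequency of AA/AT/TA/TT vs CC/CG/GC/GG
  dinucleotides at each offset in ±73 bp from the dyad; rotational
  positioning appears as a 10-bp period.
* **k-mer depletion** — per k-mer `log2(P / P_nucleosome)`, genomic
  frequency over frequency in the 147-bp windows around dyads; pentamer
  class summaries (32 A/T-only, 32 G/C-only, all 1,024).
* **TSS profiles** — midpoint rate in ±1 kb around unique TSSs, smoothed
  with a 20-bp sliding window, stratified by expression (bottom 25% /
  middle 50% / top 25% of log10 FPKM).
* **Region densities** — midpoints per bp per million fragments in
  promoter (TSS ± 500 bp) / exon / intron / intergenic labels.
* **Differential windows** — non-overlapping 200-bp tiles; conditional
  binomial test on counts, BH correction, calls at fold > 2 and
  FDR < 0.01.
* **Heptamer screen** — for each of the 4^7 = 16,384 heptamers, mean
  coverage depth over the 200-bp region around every occurrence,
  per-million normalized; ordinary least squares between each pair of
  datasets (lines, their mean, in vitro — 15 comparisons for six
  datasets); the 20 largest absolute residuals per comparison are
  outliers, reported as a union with provenance.

The simulator (`SimParams()` / `simulateDataset()`) places dyads by a
Boltzmann energy with phased A/T dinucleotides (10-bp period), poly(dA:dT)
exclusion, expression-scaled promoter architecture (NDR + phased array),
and planted per-line occupancy multipliers at chosen heptamers. See the
vignette (`vignettes/nucleosome-organization.Rmd`) for the model and every
numerical convention.

## Worked example

Simulate one study condition (200-kb genome, 43% GC, 50 genes, 2×10^5
fragments per line, heptamer AATAATA planted with a 3× occupancy
multiplier in the "eye" line) and run the core analyses:

```r
library(NucleoScope)

params <- SimParams(seed = 1)
sim    <- simulateGenome(params)
eye    <- filterFragments(sampleFragments(sim$genome, sim$truth, "eye", 2e5))
leg    <- filterFragments(sampleFragments(sim$genome, sim$truth, "leg", 2e5))
length(eye)
#> [1] 195550          # of 200,000 sampled; the 101-191 bp filter did the rest

track <- buildMidpointTrack(eye, seqlengths(sim$genome), label = "eye")
phasogramPeriod(computePhasogram(track, sim$genome))
#> [1] 10              # the 10-bp rotational signal

en <- kmerEnrichment(track, sim$genome, k = 5)
round(en$log2_ratio[c("AAAAA", "TTTTT", "CCCCC")], 3)
#> AAAAA TTTTT CCCCC
#> 1.988 2.002 -0.102  # poly(dA:dT) depleted from nucleosomal DNA

occ   <- heptamerOccurrences(sim$genome)
rates <- lapply(list(eye = eye, leg = leg), function(fr)
    heptamerRates(coverageTrack(fr, seqlengths(sim$genome)), occ))
fit <- pairwiseResiduals(rates$leg, rates$eye)
subset(selectOutliers(fit, 20), heptamer == "AATAATA")
#>   heptamer residual rank
#> 9  AATAATA 717.9503    9   # the planted motif surfaces in the top 20
```

The planted heptamer's occupancy rate is 1438.8 in "eye" versus 723.2 in
"leg" (per-million units), and it ranks 9th by absolute residual off the
leg-vs-eye best-fit line (slope 0.987) — the screen recovers the planted
3× perturbation. `runPipeline(runConfig(...))` runs the whole chain on
real or simulated inputs and writes every table with a provenance header.

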