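# repeatcomp

Chromatin compartment analysis driven by retrotransposon density, for
genome biologists studying how interspersed repeats relate to 3-D genome
organization.

Mammalian genomes fold into megabase-scale A (active) and B (inactive)
compartments, visible in Hi-C contact maps as a plaid pattern. The two
dominant retrotransposon subclasses mirror this division: LINE-1 (L1)
elements cluster in B-like heterochromatic territory, B1/Alu SINEs in
A-like euchromatic territory. `repeatcomp` provides the statistics for
quantifying that correspondence from annotation, Hi-C and imaging data:

* **De novo compartment calling from repeat density.** Per 100-kb bin,
  the union coverages of B1 and L1 are normalized to their genome
  backgrounds (f_B1 = 0.03, f_L1 = 0.19) and the log ratio
  r = log2[((d_B1 + ε)/f_B1) / ((d_L1 + ε)/f_L1)] is computed; maximal
  same-sign runs longer than 500 kb become B1-rich (r > 0) or L1-rich
  (r < 0) compartments, scored against an independent Hi-C A/B
  annotation by majority overlap.
* **Hi-C compartment statistics.** Distance-decay expectation, O/E,
  Pearson correlation matrix, anchored leading eigenvector (PC1),
  saddle plots with compartment strength (AA + BB)/(AB + BA) from the
  corner means, the homotypic/heterotypic segregation index
  S = mean(same-label contacts)/mean(cross-label contacts) per
  autosome, iterative balancing, and cross-sample compartment
  conservation with a marginal-preserving permutation null.
* **Image-based segregation index.** S_FISH = −Pearson(I_L1, I_B1) over
  in-nucleus pixels, with Otsu-based nuclear segmentation.
* **Planted-truth simulators** for repeat genomes, plaid/mitotic
  contact matrices and segregated/mixed nuclei, so every estimator is
  tested against its own generating parameter without external data.

Standard formats are supported throughout: RepeatMasker `.out`, BED,
bedGraph, chrom.sizes, dense and COO-pixel contact matrices, TIFF.

## Worked example

```r
library(repeatcomp)

sim <- simulateRepeatGenome(SyntheticGenomeSpec(seed = 1))   # 5 x 40 Mb
b1 <- binCoverage(sim$annotation, sim$genome, 1e5, "B1", prefix = TRUE)
l1 <- binCoverage(sim$annotation, sim$genome, 1e5, "L1", prefix = TRUE)
called <- callRepeatCompartments(logRatioTrack(b1, l1))
called
#> CompartmentSet: 127 regions (B1-rich: 63, L1-rich: 64)
compartmentAgreement(called, sim$truth)
#> [1] 0.9639329

m <- simulateContactMatrix(sim$truth, SyntheticHiCSpec(seed = 2))
oe <- observedOverExpected(m)
segregationIndex(oe, sim$truth, excludeChroms = character(0))
#> SegregationResult: 1 chromosome(s); autosome mean index 2.010
```

The caller recovers 96.4% of the planted compartment bases, and the
contact segregation index (2.01) sits near the planted
homotypic/heterotypic affinity ratio (1.5/0.67 ≈ 2.24); the small
deficit is the expected short-range bias of the O/E statistic, discussed
in the vignette. `runPipeline()` chains all stages and writes tracks,
BED files, tables and a JSON report; `inst/scripts/repeatcomp` wraps the
same functions for shell use.

## Package layout

* `R/` — S4 classes (`BinnedTrack`, `CompartmentSet`, `ContactMatrix`,
  `EigenTrack`, `NucleusImage`, result classes) and the analysis,
  simulation, I/O and pipeline functions.
* `vignettes/repeat-compartments.Rmd` — the methods vignette: model,
  parameter choices, simulator scope, numerical conventions,
  limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles.
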