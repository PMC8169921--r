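---
title: "Calling chromatin compartments from retrotransposon density"
author: "repeatcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin compartments from retrotransposon density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatcomp)
```

# The problem

Mammalian interphase genomes fold into two megabase-scale classes of
chromatin — the active, gene-rich A compartments and the inactive B
compartments — visible in Hi-C maps as a plaid pattern of enriched and
depleted long-range contacts. The two most abundant retrotransposon
subclasses are distributed in a strikingly complementary way: LINE-1
(L1) elements (6–7 kb, AT-rich, about 19% of the mouse genome) cluster
in heterochromatic B-like territory at the nuclear and nucleolar
peripheries, while B1/Alu SINEs (150–300 bp, GC-rich, about 3% of the
mouse genome for B1) cluster in euchromatic A-like territory in the
nuclear interior. `repeatcomp` implements the quantitative machinery for
studying this correspondence: a de novo compartment caller driven only
by repeat density, the standard Hi-C compartment statistics (eigenvector,
saddle-plot strength, homotypic/heterotypic segregation index,
cross-sample conservation), and the image-based segregation index for
two-channel FISH signals — together with planted-truth simulators so the
whole pipeline is testable without any external data.

# The density-based compartment caller

For each 100-kb bin the caller computes the union coverage fractions
$d_{B1}$ and $d_{L1}$ of the two families (elements merged before
counting; strand ignored), normalizes each to its genome background, and
takes the log ratio

$$ r \;=\; \log_2\!\frac{(d_{B1} + \varepsilon)/f_{B1}}
                        {(d_{L1} + \varepsilon)/f_{L1}}, $$

with backgrounds $f_{L1} = 0.19$ and $f_{B1} = 0.03$. Maximal runs of
same-sign bins become candidate regions — positive $r$ is B1-rich
(A-like), negative is L1-rich (B-like) — and only regions longer than
500 kb are kept. Three numerical choices matter:

* **Pseudocount** $\varepsilon = 10^{-4}$ coverage units. This is
  smaller than a single 10-bp element per 100-kb bin, so it cannot flip
  the sign of any populated bin; it only keeps empty bins finite.
* **Zero and missing bins break runs.** $r = 0$ belongs to neither
  sign; on real data it has measure zero, and treating it as a separator
  keeps the run decomposition unambiguous.
* **Discarded short runs leave gaps.** Flanking same-sign regions are
  not merged across a discarded run: the 500-kb rule is a filter, not a
  smoother, and merging would silently inflate compartment sizes.

Calls are scored against an independent A/B annotation by a majority
rule: a predicted compartment is assigned the annotation label covering
more than half of its length (exact ties and majority-uncovered regions
are "unassigned", which counts against consistency). The majority
threshold is a design choice; it is deliberately strict so that the
reported consistent fraction cannot be gamed by sprawling calls.

# Hi-C statistics

All contact statistics are cis, per chromosome, and exclude pairs closer
than 2 bins by default — the near-diagonal is dominated by
distance decay, not compartmentalization; the threshold is a parameter.

* **Expectation and O/E.** The distance-decay expectation is the plain
  mean of counts over good-bin pairs at each separation, with no
  monotone smoothing; O/E divides each pixel by it.
* **Eigenvector.** The compartment track is the leading eigenvector of
  the Pearson correlation matrix of O/E rows (computed over mutually
  good bins), re-embedded with missing values at masked bins. Its global
  sign is arbitrary, so it is anchored: the sign is chosen to correlate
  non-negatively with a B1-density track, making positive values A-like.
  Anchoring on B1 density (rather than GC or gene density) is the
  natural choice here, and the anchor is a parameter.
* **Saddle and strength.** Bins are ranked by eigenvector value and cut
  into 50 equal-occupancy quantile groups; each saddle cell is the mean
  O/E over pairs in that pair of groups. Compartment strength is
  (AA + BB)/(AB + BA) over the mean values of the extreme 20% corner
  cells. Ties in the eigenvector are broken by position ("first"), which
  only matters on synthetic two-level tracks.
* **Segregation index.** Each bin inherits the label of the compartment
  covering its midpoint. The index is the mean contact over same-label
  pairs (both labelings pooled) divided by the mean over cross-label
  pairs; the genome summary averages autosomes only, excluding chrX and
  chrY. The index can be computed on raw/balanced counts or on O/E.
  Raw counts conflate affinity with distance decay — same-label pairs
  are closer on average, so the raw index over-reads segregation —
  which is why the package's own regression checks and the simulator
  consistency analysis use the O/E form; both are exposed.
* **Balancing.** Matrices balanced upstream are accepted as-is; a
  lightweight iterative proportional fitting (50 iterations, tolerance
  1e-5 on relative marginals) is provided for raw input.
* **Conservation across samples.** Per sample and bin the label is the
  eigenvector sign; bins missing in any sample are excluded. The
  reported fractions are "modal label in at least k samples" and
  "identical in all samples". Chance levels come from a permutation null
  that independently permutes each sample's labels across bins — this
  preserves each sample's A/B marginal, which is the property a fair
  null should keep; for balanced labels it closes on the binomial tail
  form $2\,P(X \ge k)$, $X \sim \mathrm{Bin}(S, 1/2)$.

# The image-based index

The FISH segregation index of a nucleus is the negative Pearson
correlation of the L1 and B1 channel intensities over in-nucleus pixels:
+1 for perfectly segregated signals, −1 for perfect colocalization. The
definition makes it invariant to affine rescaling of either channel, so
no intensity normalization is needed. Segmentation, when no mask is
supplied, is a global Otsu threshold on the DNA channel with holes
filled and the largest connected component kept. Raw intensities are
correlated by default (the index is defined on signals, not corrected
signals); a rolling-ball-style morphological background subtraction is
optional. 3-D stacks pool all masked voxels into one coefficient rather
than averaging per-slice values, so each nucleus yields a single number.
DAPI-dense chromocenters are not excluded from the mask.

# What the simulators emulate — and what they do not

The generators plant a known truth with the statistical structure the
analysis assumes, which makes every estimator testable against its own
generating parameter:

* **Repeat genome** (`SyntheticGenomeSpec`): chromosomes (default
  5 × 40 Mb) tiled by alternating B1-rich/L1-rich blocks with log-normal
  lengths (median 1.5 Mb, log-SD 0.3 — megabase-scale blocks with
  realistic spread). L1 coverage is 0.30 in L1-blocks and 0.05 in
  B1-blocks; B1 coverage is 0.08 and 0.01; element lengths are 6–7 kb
  (L1) and 150–300 bp (B1). These coverages bracket the real genome
  backgrounds so the log-ratio contrast has guaranteed sign. Elements of
  one family never overlap each other; placement uses an exact
  order-statistics construction (sorted uniform gap offsets), which is
  uniform over non-overlapping configurations and fully vectorized.
* **Contact matrix** (`SyntheticHiCSpec`): expected counts
  $\mathrm{depth}\cdot s^{-\alpha}\cdot A$ with $\alpha = 1$, homotypic
  affinity 1.5 and heterotypic 0.67 (planted ratio 2.25), gap bins
  neutral at 1, Poisson sampling, symmetrized. The default depth of
  $10^7$ gives a mean of ~10 counts per 100-kb pixel at 1 Mb
  separation. `mitoticMode` flattens the affinity and boosts
  sub-megabase separations, giving the diagonal-dominant pattern of
  mitotic chromosomes. Poisson noise (not negative binomial) is the
  simplest model sufficient to exercise the estimators.
* **Nucleus images** (`SyntheticImageSpec`): segregated mode puts L1 in
  a rim annulus plus an inner nucleolar shell and B1 in the interior
  complement (puncta over a base level); mixed mode draws both channels
  from one shared smooth field. Poisson–Gaussian noise at SNR 10.

The simulators deliberately do **not** model polymer physics, loop
extrusion, TAD structure, replication timing, over-dispersed counts
(available as an option), microscope point-spread functions, or the
sequence composition of real repeats. Passing the planted-truth suite
therefore demonstrates that the estimators are correct and internally
consistent under the stated generative model — not that real data will
show any particular value. Quantities whose values depend on the
genuine mouse annotation and on real contact maps — genome-wide
consistent fractions, compartment counts and size distributions,
TAD-level correlation magnitudes — are therefore never asserted
anywhere in the package.

One systematic effect is worth knowing: even on O/E, the segregation
index sits a few percent below the planted affinity ratio, because
homotypic pairs are concentrated at short separations where the
expectation itself is inflated by the local predominance of homotypic
pairs. This is a property of the statistic, not a bug; the regression
suite allows for it inside its 10% band.

# Problem sizes and runtime choices

The regression and acceptance suites run on 40-Mb chromosomes at 100-kb
binning (400-bin matrices), five-chromosome genomes, 5 simulation seeds
for compartment recovery, 20 seed pairs for ordering checks, and
10,000-bin × 21-sample conservation inputs with 100 permutations. These
sizes make every eigendecomposition and pair enumeration exact and fast
while keeping all Monte-Carlo standard errors comfortably inside the
asserted tolerances.

# Worked example

```{r example, eval = FALSE}
sim <- simulateRepeatGenome(SyntheticGenomeSpec(seed = 1))
b1 <- binCoverage(sim$annotation, sim$genome, 1e5, "B1", prefix = TRUE)
l1 <- binCoverage(sim$annotation, sim$genome, 1e5, "L1", prefix = TRUE)
called <- callRepeatCompartments(logRatioTrack(b1, l1))
compartmentAgreement(called, sim$truth)

m <- simulateContactMatrix(sim$truth, SyntheticHiCSpec(seed = 2))
oe <- observedOverExpected(m)
seg <- segregationIndex(oe, sim$truth, excludeChroms = character(0))
segIndex(seg)
```

# Known limitations

* Sub-compartment (A1/A2, B1–B4 style) calling, TAD and loop calling,
  and matrix construction from reads are out of scope.
* The cooler-format reader handles a dumped plain-text pixel table, not
  the HDF5 container itself.
* Repeat content is length-weighted (union coverage). A copy-number
  weighting, which would count truncated fragments equally, is not
  implemented.
* The default statistics are cis; trans (inter-chromosomal) segregation
  is available through `transSegregation()` on a rectangular
  inter-chromosomal block, without distance normalization (no meaningful
  genomic separation exists between chromosomes).
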