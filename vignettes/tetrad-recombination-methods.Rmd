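---
title: "Tetrad recombination mapping: models, simulator and statistics"
author: "TetradRecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad recombination mapping: models, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TetradRecomb)
```

# The problem

A budding-yeast meiosis packages the four chromatids of every homolog pair
into four sequenced spores. Genotyping a dense panel of SNPs that
distinguish the two parental strains (here coded 0 for the S288c allele and
1 for the YJM789 allele) turns each tetrad into a 4 × M genotype table per
chromosome. Away from recombination events every marker segregates 2:2. A
crossover (CO) appears as two spores switching genotype in opposite
directions between two 2:2 regions; a noncrossover (NCO) appears as a short
tract of 3:1 or 1:3 segregation; crossovers often carry their own
conversion tract immediately at the exchange point.

`TetradRecomb` implements the full computational chain on such data:

1. a **synthetic tetrad generator** with known ground truth,
2. an **event caller** annotating COs, NCOs and gene-conversion tracts,
3. **crossover interference statistics** (one-pathway gamma fit,
   two-pathway gamma-mixture EM, coefficient of coincidence on 25 kb bins,
   chromatid interference),
4. the **Poisson obligate-crossover model** for nonexchange (E0)
   chromosomes,
5. descriptive genome summaries and classical **tetrad genetics**
   (Perkins distances, spore distances, viability tests).

# The simulator

## Crossover placement

Crossovers are placed on a per-chromosome *genetic* axis of length
$G_c = 50\,\lambda_c$ cM, where $\lambda_c$ is the chromosome's mean CO
count per meiosis, and mapped back to bp with a uniform cM/bp scale. Two
pathways contribute:

* **Class I (interfering)**: a stationary gamma renewal process with shape
  $\nu$ and rate $\nu p/50$ per cM, so the expected count is
  $p\,\lambda_c$. The first inter-event distance is drawn from the
  equilibrium (length-biased residual) distribution — sampled as
  $U \cdot X$ with $U \sim \mathrm{Unif}(0,1)$ and
  $X \sim \Gamma(\nu + 1, \text{rate})$ — so event density is uniform along
  the chromosome and there is no edge depletion. With $\nu = 1$ the
  process is exactly Poisson.
* **Class II (noninterfering)**: a homogeneous Poisson process with mean
  $(1-p)\lambda_c$.

Each crossover involves one chromatid of each homolog, drawn uniformly
from the four nonsister combinations, independently per crossover — the
no-chromatid-interference null, under which adjacent crossover pairs are
2-, 3- and 4-strand doubles in 1:2:1 proportion.

Rendering genotypes from a crossover list must respect that the labels in
the truth table are *parental chromatid* labels while a spore is a mosaic:
the renderer tracks, along the chromosome, which parental chromatid each
spore strand is currently reading and swaps the futures of the two strands
reading the exchanged chromatids. This guarantees every crossover is a
visible reciprocal two-spore switch, also after arbitrary upstream
exchanges.

## Gene conversion

Tract lengths follow a geometric law on bp with a configured median
(`co_gc_tract_median_bp`, `nco_gc_tract_median_bp`). Only medians are
reported for the study system; the geometric choice is the package's own
(memoryless resection/repair), and because the caller estimates lengths
from marker spans, only the median scale materially matters at the tested
marker densities. A crossover carries an associated tract with probability
`coGcProb` (default 0.7 — in dense hybrid maps the majority of crossovers
show a detectable conversion tract), placed on one of its two chromatids,
on a random side of the breakpoint. NCO tracts are Poisson per chromosome
on a single uniformly drawn chromatid. Complex multi-chromatid conversion
classes are available through `complexRate` but default to 0.

## Default conditions

The per-genotype presets (`presetParams()`) carry the study conditions:
genome-wide CO/NCO means 93.4/46 (wild type, 66 tetrads), 64.4/49.5
(*mlh3*, 19), 136.5/85.9 (*pch2*, 15), 99.8/93.6 (*mlh3 pch2*, 20);
one-pathway shapes 1.83, 1.29, 1.33, 1.13; CO-associated/NCO tract medians
2.0/1.5, 2.4/1.7, 2.7/1.8 and 3.9/2.2 kb. The wild-type tract medians are
not reported in the study and were fixed once at values typical of
S288c/YJM789 maps. Genome-wide means are spread over chromosomes as
$\lambda_c \propto L_c + L_0$ with $L_0 = 100$ kb: the baseline gives
small chromosomes the known excess of crossovers per kb (chrI receives
about 2.2 COs per meiosis at the wild-type total, about twice its share by
length alone). Markers (59,215 by default, emulating the genotyped SNP
density) are allocated proportionally to physical length and placed
uniformly.

What the generator does **not** emulate: real SNP clustering and gaps
(markers are uniform), genotyping error, aneuploidy and copy-number
artefacts, homolog-biased DSB formation, crossover homeostasis, and
centromere/telomere suppression of events (placement is uniform on the
genetic axis). Round-trip tests therefore certify the annotation and
statistical machinery under the model's assumptions, not the upstream
genotyping pipeline.

# The event caller

Markers with any missing call are excluded from block logic, never
imputed. Maximal runs of identical 4-spore genotype vectors form blocks,
classed by segregation. Between consecutive 2:2 blocks the set of
switching spores determines crossovers: two spores in opposite directions
= one CO; four spores, two up and two down = a 4-strand double (two COs on
the same interval; the pairing of up- with down-switching spores is not
identifiable and is fixed arbitrarily). Any unbalanced flank change is
flagged `GC_complex` rather than dropped. The breakpoint is reported at
the midpoint of the flanking-marker gap — the convention is arbitrary and
symmetric.

Non-2:2 blocks become conversion tracts. The converted chromatids are
judged against the flanking 2:2 vectors; when the flanks differ (a CO
spans the gap) the smaller of the two candidate sets is taken, with ties
resolved toward the right flank — the tie is a genuine annotation
ambiguity for conversion tracts abutting a breakpoint. A tract inside a
crossover gap whose converted chromatid is one of the crossover chromatids
is attached to that crossover (`co_associated`), subject to a 5 kb
association window (`mergeGapBp`, configurable; the upstream study's exact
association parameters are not published). Tract lengths are reported as
minimum (converted-marker span), maximum (distance between the nearest
non-converted flanking markers) and their midpoint, the default summary.

Nonexchange (E0) chromosomes are chromosomes with zero called COs in a
meiosis. Because weak interference permits closely spaced double
crossovers that can masquerade as two NCO tracts, `flagAmbiguousE0()`
flags E0 chromosomes carrying two opposite-direction single-chromatid
tracts on nonsister chromatids within 10 kb (configurable) as admitting
re-annotation as a double crossover, and reports whether the chromosome
shows any conversion at all.

# Interference statistics

## Genetic-scale conversion

Inter-crossover distances are taken between adjacent CO midpoints per
chromosome per tetrad and converted to cM with the uniform per-chromosome
scale $50\,\bar\lambda_c / L_c$ cM/bp, where $\bar\lambda_c$ is that
genotype's mean CO count on the chromosome — so genotypes with different
crossover frequencies are compared on a common scale, and uniform
rescaling of all rates leaves the distance distribution invariant.
Distances are pooled across chromosomes and tetrads (a per-chromosome fit
is available by subsetting events). Censoring at chromosome ends is
ignored: only distances between observed adjacent crossovers enter,
which leaves a small positive truncation bias in fitted shapes
(about +0.02 at the study's sample sizes, well inside the reported
precision).

## One-pathway gamma fit

The two-parameter gamma MLE: the shape solves
$\log\hat\gamma - \psi(\hat\gamma) = \log \bar d - \overline{\log d}$
(solved by bisection on the log scale to $10^{-12}$), and the rate is
$\hat\gamma/\bar d$. $\gamma = 1$ is no interference; $\gamma > 1$
positive interference. The fit is verified in the test suite against a
0.001-step grid-search oracle and an independent general-purpose fitter.

## Two-pathway gamma-mixture EM

The density $p\,\Gamma(d;\nu,r_1) + (1-p)\,\Gamma(d;1,r_2)$ fixes the
Class II shape at 1 (the noninterfering exponential pathway). The E-step
computes responsibilities; the M-step updates $p$ and the rates in closed
form and $\nu$ from the responsibility-weighted score equation, so the
log-likelihood is non-decreasing. Initialization is the pooled one-pathway
fit with $p_0 = 0.5$ plus 5 seeded random restarts; the best likelihood is
kept. EM stops when the gain drops below `tol` ($10^{-8}$) or after
`maxIter` (1000). A mixing proportion collapsing below $10^{-6}$ (or above
$1-10^{-6}$) marks the fit degenerate: the two components are not
identifiable on such data and the fit reduces to one pathway.

## Coefficient of coincidence

Each chromosome is cut into 25 kb bins; $p_i$ is the fraction of tetrads
with at least one CO midpoint in bin $i$. For every same-chromosome bin
pair the observed double count (tetrads hitting both bins) is compared
with $n\,p_i p_j$; pairs with zero expected frequency are excluded, and
pairs are grouped by the physical gap between the bins, so adjacent bins
form the 0–25 kb class. CoC per class is the mean ratio over qualifying
pairs; interference is $1 - \mathrm{CoC}$ at the adjacent class.
Cross-chromosome pairs are excluded. Two genotypes are compared by a 2 × 2
chi-square on (observed, expected − observed) totals in the adjacent
class, replaced by a Fisher exact test when an expected cell drops
below 1.

# The obligate-crossover model

Under independent crossovers, chromosome $c$ is E0 with probability
$e^{-\lambda_c}$ and a meiosis avoids E0 entirely with probability
$\prod_c (1 - e^{-\lambda_c})$ — computed by `poissonNoE0()`, with
`noE0Curve()` sweeping the genome-wide mean at fixed allocation weights.
The model is validated against a Monte-Carlo oracle that draws per-
chromosome counts from the same renewal construction as the simulator.
Observed E0 fractions come with an exact binomial test against a reference
proportion. The published per-chromosome means behind the study's expected
percentages are supplementary data not redistributed here; when those are
unavailable the package reconstructs $\lambda_c$ from a genome-wide mean
with the default allocation weights, which reproduces the published
expected percentages to within 1–3 percentage points.

# Tetrad genetics

Two-locus tetrads are classed PD/NPD/TT by the standard definitions, and
map distances use the Perkins equation
$\mathrm{cM} = 100\,(TT/2 + 3\,NPD)/n$, additive over intervals.
Spore-based distances are the raw recombinant fraction × 100 with no
mapping-function correction, so they undercount double crossovers and
never exceed the tetrad-based estimate (equality iff NPD = 0, asserted
exhaustively in the tests). Viability tables are compared by Fisher's
exact test on pooled (viable, dead) spore counts, and the Meiosis I
nondisjunction signature is the excess of the even viable-spore classes,
$(f_4 + f_2 + f_0) - (f_3 + f_1)$.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed in memory; event tables are written
  0-based half-open (BED) and converted back on read.
* Gamma fitting requires ≥ 2 strictly positive distances; all-equal
  distances make the score equation unsolvable and raise an error.
* Zero-rate chromosomes are legal in the simulator (guaranteed E0) and
  excluded with a warning from cM conversion.
* Welch's t-test is used for per-chromosome comparisons (the upstream
  study names only "t-test") with a zero-variance equality shortcut;
  Mann–Whitney for tract-length comparisons; per-chromosome p-values are
  reported raw with an optional Benjamini–Hochberg column.
* Crossover breakpoints that collide at the same bp after rounding are
  de-duplicated in the generator; duplicate breakpoints in a user truth
  table are an error in the renderer.

# Problem sizes in the test suite

The suite calibrates at sizes chosen to make each check decisive while
keeping a full run in a few minutes: 200 full-density tetrads for the
simulator–caller round trip (≥ 99% recovery of crossovers separated from
neighbouring events by an informative 2:2 marker), 2000 truth-level
tetrads for the Poisson CoC and shape-1 calibrations, 20 replicates of the
published-shape recovery experiments, 10 × 5000 distances for EM
parameter recovery, and 20,000 Monte-Carlo meioses for the no-E0 model.

# Known limitations

* The caller assumes biallelic 0/1 markers and four viable spores; it
  does not phase around missing data and treats any ambiguous flank
  change as `GC_complex` rather than attempting rescue.
* Tract-direction ties at crossover-associated tracts (which chromatid of
  the pair converted) are resolved by convention, not inference.
* The cM conversion assumes uniform recombination density within a
  chromosome; real maps are locally nonuniform.
* The two-pathway EM can be weakly identified when the interfering shape
  is near 1; inspect the `degenerate` flag and the likelihood trace.
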