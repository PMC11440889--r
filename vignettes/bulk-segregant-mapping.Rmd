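---
title: "Mapping QTL from pooled bulks and scanning for selective sweeps with bulkQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL from pooled bulks and scanning for selective sweeps with bulkQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

bulkQTL implements the computational path from pooled allele read depths to
QTL intervals and candidate genes that is standard in bulk segregant
analysis (BSA) of crosses such as the silkworm backcross populations used
to dissect cocoon-shell ratio: per-SNP SNP-index and delta(SNP-index) with
Monte-Carlo confidence intervals, the G statistic with tricube smoothing
and data-driven log-normal p-values, windowed selective-sweep scans (pi,
F_ST, reduction of diversity) over population panels, and a rule-based
candidate-gene screen against gene models and tissue expression. A forward
simulator of the whole experiment makes every stage testable at desk scale
with known truth.

# The bulk-segregant model

In a BC1 design (F1 x recurrent parent), every individual is, at each
locus, either homozygous for the recurrent-parent (reference) allele or
heterozygous, each with probability 1/2. Pooling any random set of
individuals therefore yields an expected donor (alternate) allele
frequency of 0.25, so sequencing reads drawn from a pool carry the
reference allele with expected frequency 0.75, and the **SNP-index** of a
bulk — the alternate-allele fraction of the reads,

$$\mathrm{SNP\text{-}index} = \frac{\mathrm{alt\ depth}}{\mathrm{ref\ depth} + \mathrm{alt\ depth}}$$

— is centred on 0.25. These two quantities are the standard sanity checks
on a BC1 pooling experiment, and the package's acceptance checks recompute
both from a simulated null design.

Near a QTL the phenotypic-extreme bulks become enriched for alternative
genotypes, and

$$\Delta(\mathrm{SNP\text{-}index}) = \mathrm{SNP\text{-}index}_{H} - \mathrm{SNP\text{-}index}_{L}$$

departs from 0. Under perfect selection at a fully penetrant BC1 QTL the
high bulk is entirely heterozygous (index 0.5) and the low bulk entirely
homozygous-reference (index 0), so 0.5 is the theoretical ceiling of
delta(SNP-index); this enumeration is frozen into the test suite.

Significance is assessed two ways, mirroring the two established BSA
statistics:

* **Simulated confidence intervals.** `simulateCI()` draws, for each read
  depth on a grid, the composition of both bulks under the cross design,
  the true bulk allele frequencies, and binomial read sampling, 10,000
  times by default, and records the 95th and 99th percentiles of
  |delta(SNP-index)| — two-sided thresholds CI_95 and CI_99. Simulating on
  a depth grid and interpolating linearly to each SNP's observed mean
  per-bulk depth (constant beyond the grid) avoids re-simulating per
  distinct depth; the threshold is smooth in depth, so interpolation error
  is far below Monte-Carlo error.
* **G' analysis.** The G statistic is the log-likelihood-ratio of the 2x2
  allele-by-bulk read-count table, smoothed per chromosome with a tricube
  kernel over a physical window (`Gprime`). The null is estimated from the
  data: sites with G' above a Hampel outlier bound (median + 5.2 MAD) are
  set aside as putative signal, a log-normal is fitted to the remainder by
  moments of log G', right-tail p-values are taken from that fit, and
  genome-wide Benjamini-Hochberg q-values control the FDR. The Hampel
  bound is applied on the raw G' scale; the 5.2 multiplier is the
  conventional robust-outlier constant.

QTL regions are maximal runs of consecutive SNPs exceeding the chosen
threshold (smoothed |delta| above CI_95/CI_99, or q-value below the FDR);
each region reports its span, peak SNP, and SNP support. We deliberately
report a single maximal run per threshold and do not attempt to split
closely linked peaks — resolving a region into multiple loci needs
recombinant-based evidence the pooled design does not carry.

# Tunable parameters

* `windowBp` (default 1e6 bp): physical width of the smoothing window for
  both delta(SNP-index) and G. One megabase is the scale at which BC1
  linkage blocks (tens of cM per chromosome) still average tens of SNPs at
  typical marker densities. Both tricube (default) and plain-mean
  smoothing are available.
* `FilterSpec()` defaults: pooled reference-allele frequency within
  [0.10, 0.90], combined depth in [100, 500] reads, per-site bulk depth
  difference at most 100, at least 40 reads per bulk, genotype quality at
  least 99, plus conventional variant-call hard filters applied when the
  annotation columns exist. `depthDifference` is interpreted as the
  maximum |depth_H − depth_L| per site and the total-depth bounds as
  bounds on depth_H + depth_L; both interpretations are configurable
  facts of the implementation, stated here because filtering tools vary.
  Each removed site is attributed to the *first* rule it fails, in the
  declared order, which makes removal logs additive and auditable.
* `simulateCI(reps)` (default 10,000; minimum 100): Monte-Carlo error of
  the 99th percentile at 10,000 reps is ~2% of the threshold value.
* Sweep scan: 5-kb windows on a 500-bp step grid anchored at position 1,
  per chromosome, reported 1-based inclusive. Domestication-stage cutoffs:
  F_ST top 1%, derived-population pi bottom 5%, ROD top 5%; the
  improvement stage relaxes F_ST to the top 5%. Quantiles are empirical
  type-7 quantiles — stated explicitly because quantile conventions
  differ between toolchains. Windows with fewer than `minSnps` (default
  3) usable sites in any track are dropped before ROD is computed
  (`harmonizeWindows()`), formalising the manual deletion/filling of
  sparse windows that such scans otherwise require.
* F_ST uses the Hudson estimator as ratio-of-averages over the window
  (robust to rare variants and to unequal sample sizes); a Weir-Cockerham
  mode is provided for comparability. Raw values are kept alongside
  values clipped to [0, 1].
* ROD = 1 − pi_derived / pi_ancestral, with the ancestral panel (Wild for
  domestication, Local for improvement) in the denominator; undefined
  where ancestral diversity is 0, negative values reported unclamped.
* Candidate screen: regulatory flank of 2 kb, strand-aware upstream-only
  by default (symmetric flanks opt-in); an intergenic-only segment falls
  back to the single nearest gene by bp distance to its variants, with
  equidistant ties reported and flagged. The silk-gland expression rule
  requires mean FPKM > 10 in at least one silk-gland section *and* a
  silk-gland share of at least 20% of total expression. Exonic status of
  a variant is positional (inside an annotated exon), a deliberate proxy
  for effect-class annotation, which is out of scope. Variant
  significance uses the raw Pearson chi-square p < 0.05 (1 df, no
  continuity correction); a BH-adjusted column is also emitted.

# What the simulator emulates — and what it does not

`simulateBc1Bulks()` generates a BC1 population with linkage (two-state
Markov chain along each chromosome under a Haldane map, default 3 cM/Mb —
a typical lepidopteran recombination density, and the reason mapped QTL
regions have megabase-scale width), a phenotype composed of major-QTL
effects, an optional polygenic background (`h2Background`, default 0.3,
spread over all markers with random signs), an optional rearing-block
("moth area") effect, and Gaussian noise. The extreme 10% tails are bulked
(160 individuals per bulk at the default design) and read depths are drawn
negative-binomially around 160x per bulk (dispersion 50, reproducing a
250-400x combined-depth spread; Poisson optional) with binomial allele
sampling, and an optional symmetric sequencing-error flip (default 0,
since real pipelines filter rather than model errors).

It does **not** simulate raw reads, sex linkage (real designs often use
males only), coalescent-exact genealogies, or genotyping error structure;
passing tests therefore demonstrate the statistical machinery, not
robustness to alignment or calling artifacts. The polygenic model is a
stand-in for an unknown genetic architecture, not an estimate of it.

One modelling consequence worth stating: with a polygenic background,
whole chromosomes drift together in the bulks (linked small effects act
like weak chromosome-scale QTL), so per-bulk mean SNP-index fluctuates
beyond binomial noise on small genomes. Null calibration experiments
therefore set `h2Background = 0` — the null of interest is "no
genotype-phenotype association", and the 0.75/0.25 expectations hold
exactly only under it.

`simulateThreePopulations()` scatters biallelic sites uniformly, draws
ancestral frequencies from Beta(0.8, 0.8) conditioned on polymorphism,
drifts each panel around them (Beta with concentration 60, chosen to give
wild-vs-domestic background F_ST of a few percent), and shrinks
minor-allele frequencies toward fixation inside the swept interval by
`sweepStrength` in the derived panels (default: both Local and Improved,
since a domestication sweep persists through later breeding). Default
panel sizes are 102/410/388 haplotypes, i.e. twice the 51/205/194 strains
of the motivating study design. A complete sweep (strength 1) fixes every
site in the interval, so windowed pi is exactly 0 and ROD exactly 1 there
— an anchor used in the tests. The generator produces no linkage
disequilibrium between sites and no demographic history; it is sufficient
for frequency-based statistics (pi, F_ST, ROD), not for haplotype-based
ones.

# Numerical choices and degenerate inputs

* Zero-depth sites make SNP-index undefined; the low-level functions
  refuse them and `computeBulkStats()` drops them with a logged count.
* G of a table with a zero margin is 0 by convention (a degenerate table
  carries no evidence), and 0·ln(0/e) ≡ 0 term-wise.
* Tricube weights are normalised per focal SNP; an isolated SNP keeps its
  own value. Smoothing is exact (no binning): cost is O(n·k) per
  chromosome, trivial at desk scale.
* If the trimmed log-G' sample has zero variance, all p-values are 1 —
  a flat statistic contains no outliers by definition.
* Phenotype ties at the bulk boundary are broken by stable individual
  index, making bulking a deterministic function of (seed, design).
* All internal coordinates are 1-based inclusive (VCF/GFF convention);
  conversion to BED's 0-based half-open happens exactly once, in
  `writeRegionBed()`.
* F_ST windows with zero denominator, pi windows with no usable site, and
  ROD with zero ancestral diversity are missing values, never zeros, and
  windows must clear `minSnps` in every track to enter the joint
  criterion.

# Problem sizes used by the tests

Unit tests run on populations of ~400 individuals and genomes of a few
megabases. The statistical acceptance checks use the full study-scale
null design — 1600 individuals, 160 per bulk, 160x per-bulk depth — on a
28-chromosome genome (16 Mb each, one marker per 80 kb; 5600 markers),
sizes chosen so that chromosome-scale drift of bulk composition averages
out and the 0.75/0.25 expectations are tested to ±0.01. CI calibration
uses 10,000 simulation replicates per depth and 10,000 independent null
SNPs; QTL recovery uses 20 replicates of a two-chromosome genome (10 Mb
each) with a fully penetrant mid-chromosome QTL, where linkage arithmetic
(3 cM/Mb, Haldane) keeps the whole QTL chromosome inside one contiguous
CI_99 run. Sweep recovery scans 1 Mb containing a 10-kb complete sweep —
about 1% of the sequence, the regime a top-1% F_ST cutoff presumes.

# Known limitations

* Two bulks only; multi-bulk designs and recombinant-count interval
  refinement are out of scope.
* The BC1 null is exact; the F2 option models allele sampling but has no
  matching phenotype simulator.
* The G' null fit assumes the genome is mostly null; a genome saturated
  with signal would inflate the fitted null and cost power.
* Candidate screening is positional and rule-based; it does not predict
  variant effects, protein domains, or structural variation.
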