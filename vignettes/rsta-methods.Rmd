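---
title: "Restriction Site Tiling Analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction Site Tiling Analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay

Restriction Site Tiling Analysis (RSTA) genotypes a population at
thousands of restriction cut sites simultaneously. Genomic DNA from each
diploid individual is split into two fractions: one digested with a
4-base cutter (TaqαI, recognition site TCGA) and labelled green (Cy3),
the other left undigested and labelled red (Cy5). Both fractions
co-hybridize to an array of 50-bp tiles, each centered on one genomic
TCGA site. An allele carrying the intact site is cut in the digested
fraction and stops binding its tile, so the tile's log~2~(Cy5/Cy3) ratio
is high; an allele with a mutated site escapes digestion and binds both
fractions equally, so the ratio is low; heterozygotes are intermediate.
Discovery and genotyping happen in one experiment, so the method has no
ascertainment bias.

`rsta` implements the complete desk-scale analysis: tile design from a
genome FASTA, a hybridization simulator that generates realistic
two-channel data with known truth, signal aggregation and QC, genotype
and indel calling, and population genetics on the resulting genotype
matrix.

## Tile design

`scan_recognition_sites()` reports every motif occurrence (overlapping
ones included; windows containing N never match). On i.i.d.
equal-frequency sequence a 4-bp site occurs once per 4^4 = 256 bp, which
is both a design-capacity estimate (`projected_tile_yield()`) and a
property test for the scanner. `design_cut_site_tiles()` centers a
50-bp window on each site (23 bp flanking each side); all coordinates in
the package are 0-based, half-open. When two sites are close enough that
their tiles would overlap, *both* tiles are dropped — a symmetric rule
that avoids any dependence on scan order.

Cross-reactive tiles are removed by `uniqueness_filter()`, an exact-seed
(k = 10) plus ungapped-extension alignment screen: a tile is excluded
when more than one genome location (origin included, both strands)
matches it above 90% identity over the full tile. At that threshold a
hit can carry at most 4 mismatches over 50 bp, and 4 mismatches always
leave an exact run of at least 10 bases, so the 10-mer seed provably
misses nothing; the screen therefore agrees exactly with a brute-force
all-positions oracle, which the test suite verifies.

Control classes mirror standard array practice: noncut tiles centered on
a motif one substitution away from the cut site (TTGA) behave like
always-uncut loci; negative controls are random 50-mers with zero genome
hits (background level); positive controls are windows of a supplied
multi-copy sequence such as rDNA; and a degradation series carries 1–10
deliberate mismatches per tile (11 tiles per base tile) to calibrate
hybridization loss.

## The hybridization simulator

`simulate_dataset()` renders diploid genotypes into per-tile,
per-replicate two-channel intensities so that every downstream module is
testable without any external data. Its defaults are the study
conditions the package targets: 2 populations × 10 individuals, 24% of
loci polymorphic, 3% of polymorphic loci carrying a deletion allele,
triplicate tiles, replicate noise CV 0.08, and control-class sizes at
the published platform's ratios (noncut 10,523 : negative 1,036 :
positive 100 per 50,935 cut-site tiles).

Binding loss is exponential in the number of tile/sample mismatches,
`eff(m) = exp(-λ m)`, with λ = ln(5)/4 anchored to the single calibrated
point available: an 80% intensity reduction at four mismatches in a
50-bp tile (`binding_efficiency(4) = 0.20`). The same curve implies that
8% sequence divergence (4/50) brings a tile to near-background signal.

Per tile, a full-binding intensity I0 is drawn once, uniform on
[150, 1000] fluorescence units, and each allele contributes half a dose:
the Cy5 (undigested) contribution is `I0/2 · eff(allele)` with eff = 1
for the cut allele, `eff(1)` for a point mutation in the site, and
~0 for a deletion overlapping the tile. Both channels receive additive
background and multiplicative log-normal noise per replicate.
Heterozygote signal is the sum of the two half-doses; the data only
constrain the heterozygote to lie between the homozygotes, and additive
half-doses are the simplest mechanism consistent with that.

Two parameters required deliberate calibration:

* **Digestion efficiency (default 0.8).** An idealized digestion would
  remove the cut allele from the Cy3 channel completely. Under the
  mandated slide-sum PMT normalization, however, complete digestion
  places the noise-free heterozygote cluster at about −0.6 — exactly on
  the boundary of the heterozygote calling window — so fixed-threshold
  calling would be a coin flip. Real digests are incomplete, and the
  residual binding compresses the cluster geometry the way real arrays
  show it. The default (80% of cut-allele material digested away) is
  chosen so that, at the default array composition and mean tile
  intensity, the noise-free heterozygote log ratio sits at the midpoint
  (−0.35) of the −0.6…−0.1 heterozygote window after normalization.
* **Background (default 10 units).** The background enters both
  channels additively, so it controls how much the heterozygote cluster
  position drifts with tile brightness; a low background keeps that
  drift small (≈0.07 log units across the I0 range) while staying
  clearly inside the "deletion" zone: deletion alleles read at
  background (≈10 < 50) and normal-binding tiles at I0 + b ≥ 160 > 150,
  so the absolute indel cutoffs are meaningful on simulated data.

PMT normalization (`apply_pmt_normalization()`) rescales the Cy5 channel
by one scalar so the slide-wide channel sums match, emulating dynamic
scanner-gain equalization. All log ratios shift by a common constant; on
a cut-site-dominated array that shift (≈ −1.25 at the defaults) pushes
the uncut-homozygote cluster below zero, reproducing the offset the
fixed thresholds assume.

### Population structure in the simulator

Population allele frequencies follow the Balding–Nichols model: a Beta
distribution with mean p (the ancestral frequency) and variance
F·p(1−p). For a finite number of demes r the realized G~ST~ of such
draws is not F: its expectation is approximately F(r−1)/r / (1 − F/r).
Because the simulator exists to provide truth with a *known* F~ST~, the
`fst_sim` parameter of `population_spec()` is defined as the among-deme
G~ST~ the truth table carries, and `simulate_genotypes()` converts it
internally to the Balding–Nichols parameter `v = r·fst_sim /
(r − 1 + fst_sim)`, which makes the H~T~-weighted G~ST~ of the true
per-population frequencies converge to `fst_sim` as loci accumulate.
`draw_allele_frequencies()` itself keeps the literal Balding–Nichols
semantics for the parameter you pass it.

## Signal processing

Replicate intensities are averaged per channel *before* the ratio
(robust to single-replicate dropouts); the per-locus log ratio is
log~2~(mean Cy5 / mean Cy3), undefined (and flagged) when a channel mean
is non-positive. `replicate_cv` is sd/mean of the per-replicate log
ratios; note that its scale depends on the log-ratio's distance from
zero, so the QC report also gives the per-channel intensity CV, which
matches the simulator's `noise_cv` directly.

Loci whose across-individual mean Cy5 signal does not exceed the 95th
percentile of the negative controls are masked as poor-binding (a real
phenomenon concentrated in fast-evolving regions: heavily diverged
sample DNA simply stops hybridizing) and excluded from calling. The
channel used (Cy5) and the quantile are choices of this package; the
quantile is an exposed parameter.

## Polymorphism identification and genotype calling

A locus is *polymorphic* when (a) the range of its 20 per-individual log
ratios exceeds 0.7 and (b) a univariate Gaussian mixture model selects
more than one component. The mixture is fit by EM with
component-specific variances for k = 1…4 (allowing a fourth component
makes the selection settle on three more reliably), k-means++-style
seeded initialization, 10 restarts, a relative log-likelihood
convergence tolerance of 1e-8, at most 500 iterations, and a small
variance floor (1e-3 of the sample variance) that keeps zero-noise
point-mass clusters finite. Model selection maximizes BIC =
2·logL − (3k−1)·log n. When the range rule already fails, the clustering
is skipped — the conjunction cannot hold, and the short-circuit keeps
genome-scale runs fast. The unequal-variance univariate family is the
1-D analogue of the spherical unequal-volume ('VII') parameterization
used by reference mixture software, against which the fitter is
cross-checked in the test suite.

Genotypes at polymorphic loci are called with fixed thresholds on the
normalized log ratio: below −0.6 homozygous uncut, above −0.1 homozygous
cut, between them heterozygous. The boundary values themselves are
assigned to the heterozygote class — a measure-zero choice the data
cannot distinguish. Thresholds, the 0.7 range rule, and the indel
cutoffs are all exposed parameters with these defaults.

Indel loci are detected on the *pre-normalization* Cy5 scale (absolute
cutoffs only make sense there): a locus is flagged when the Cy5 mixture
selects 2–3 clusters with at least one cluster mean below 50 (deletion
alleles at background) and one above 150 (normal binding). Deletion
dosage follows cluster rank: lowest cluster = 2 deleted alleles, highest
= 0, middle = 1. Rank, not the absolute cutoffs, assigns the dosage,
because the heterozygote cluster of a bright tile sits well above 150.
A deletion allele contributes to *neither* channel, which pushes
deletion heterozygotes toward the cut-homozygote log-ratio cluster;
genotypes at indel loci therefore come from the Cy5 dosage, and the
log-ratio concordance metric is computed over point-mutation loci.

## Population genetics

Per-locus F~ST~ is the G~ST~ form: H~i~ = 2p~i~(1−p~i~),
H~S~ = mean(H~i~), H~T~ = 2p̄(1−p̄) at the equally weighted mean
frequency, F~ST~ = (H~T~ − H~S~)/H~T~ (NA when H~T~ = 0). With equal
weights and pooled means this estimator cannot go negative. Missing
genotypes are handled by per-locus pairwise deletion; loci with fewer
than half the individuals called in either population are excluded.

The plug-in estimator carries a finite-sample bias of roughly +1/(4n)
(+0.025 at n = 10 diploids per population) because sampling noise in
p̂ inflates the between-population variance. For parameter-recovery
validation, `fst_locus()`/`fst_table()` therefore offer `correct =
TRUE`, the Nei–Chesser small-sample corrections (H~S~ scaled by
2n/(2n−1); H~T~ incremented by H~S~/(2n̄r)), under which the
H~T~-weighted genome-wide estimate recovers the simulated F~ST~ within
±0.01 across the 0–0.2 range. The uncorrected form remains the default
everywhere, and the genome-wide summary defaults to the simple mean
over loci (the H~T~-weighted ratio of sums is available via
`fst_overall(weight = "ht")`).

The panmixia test shuffles the 2n called allele copies of each locus
across all individuals and deals them back into the populations,
recomputing F~ST~ each time. Dealing allele copies into pools is
distributionally identical to a multivariate hypergeometric draw, which
is how the permutation is implemented — vectorized over loci and
permutations, making 10,000 permutations on thousands of loci a
seconds-scale operation. Summaries follow the conventional readout: the
mid-rank of the observed mean among permuted means (uniform on [0,1]
under panmixia, verified by a 200-replicate calibration study), the
fraction of permutations with a narrower (smaller-sd) F~ST~
distribution, a KS comparison of the observed distribution against the
rank-averaged permuted distribution, and excess counts of loci above an
F~ST~ tail cutoff (default 0.2). An individual-label permutation mode is
provided for sensitivity analysis.

Remaining analyses are standard: per-individual observed heterozygosity
(fraction of heterozygous calls) with a KS comparison between
populations; per-locus, per-population 1-df Hardy–Weinberg chi-square
tests with Benjamini–Hochberg correction (tests with any expected count
below 1 are flagged low-power); centered covariance PCA of individuals
(loci as variables) on the three conventional locus subsets (all
polymorphic, excluding the top-F~ST~ tail, tail only, with the tail
defined as mean + 2 sd); Pearson correlation of F~ST~ between paired
coding/upstream loci with a pair-permutation p-value; a pairwise LD
screen by permutation chi-square on the 3×3 genotype table (an explicit
simplification of an exact genotypic LD test — the Markov-chain exact
test is not reimplemented here); and Fisher's combined probability test.

## Problem sizes and verification

The test suite and the acceptance script exercise the package at desk
scale, chosen to complete in minutes on one CPU: genotype concordance
and sensitivity on 2,000-locus × 20-individual simulations (≥99%
concordance at the default noise CV of 0.08, exactly 100% at zero
noise); F~ST~ recovery on 5,000-locus panels at F~ST~ ∈ {0, 0.003, 0.05,
0.2}; BIC component-count recovery on 6-sd-separated mixtures of 100
points (≥95% of trials); permutation-test calibration over 200 null
datasets of 250 loci at 500 permutations each; and exact agreement of
the uniqueness screen, allele counting, F~ST~, Benjamini–Hochberg and
Fisher's test with brute-force oracles on small instances. Accuracy
metrics are measured against *sample* truth — loci polymorphic among
the 20 sampled individuals — since loci monomorphic in the sample are
undetectable by any genotyping method.

## Limitations

The simulator does not model dye bias, spatial artifacts, scanner
saturation, or sequence-dependent hybridization thermodynamics, so
passing tests demonstrate the pipeline's statistical behaviour under
the stated physics, not robustness to those artifacts. Tile design
screens uniqueness with an ungapped identity measure (no gapped
alignments, no melting-temperature model). Genotype calling uses the
global fixed thresholds throughout rather than per-batch refits. SNPs
outside the recognition site, phasing, and imputation of missing calls
are out of scope, as are coalescent-based outlier-detection methods;
the package stops at the per-locus F~ST~ distribution and its
permutation null.
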