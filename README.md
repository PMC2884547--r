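# rsta — Restriction Site Tiling Analysis

Genotyping thousands of loci in a non-model species without sequencing
every individual: Restriction Site Tiling Analysis (RSTA) digests each
individual's genomic DNA with a 4-base restriction enzyme (TaqαI, site
TCGA), labels the digested fraction green (Cy3) and an undigested
fraction red (Cy5), and co-hybridizes both to an array of 50-bp tiles
centered on genomic cut sites. An intact ("cut") allele disappears from
the digested fraction, so its tile shows a high log₂(Cy5/Cy3) ratio; a
mutated ("uncut") allele escapes digestion and binds both fractions,
giving a low ratio; heterozygotes are intermediate. Because discovery
and genotyping happen in the same hybridization, the method has no
ascertainment bias.

`rsta` is a desk-scale, end-to-end implementation for population
geneticists and method developers:

* **Tile design** from a genome FASTA: recognition-site scanning,
  cut-site-centered 50-bp tiles, non-overlap and uniqueness screening
  (seed-and-extend alignment, >90% identity rule), genomic-context
  classification (coding / upstream / intergenic), control tiles
  (non-cut motif, negative, positive) and a mismatch degradation series.
* **Hybridization simulation**: diploid genotypes for structured
  populations (Balding–Nichols frequencies with a known realized F_ST),
  rendered into replicate two-channel intensities under exponential
  mismatch decay calibrated to 80% signal loss at four mismatches.
* **Signal processing**: PMT (slide-sum) normalization, replicate
  aggregation into per-locus log-ratio and Cy5 matrices, KS-based QC,
  poor-binding masking against negative controls.
* **Calling**: polymorphic loci by a log-ratio range rule (>0.7) plus
  univariate Gaussian-mixture clustering with BIC (EM, 1–4 components);
  three-state genotypes by fixed thresholds (−0.6 / −0.1); indel loci
  from low/high Cy5 clusters (<50 / >150).
* **Population genetics**: allele frequencies, per-locus
  F_ST = (H_T − H_S)/H_T, individual heterozygosity, Hardy–Weinberg
  chi-square tests with Benjamini–Hochberg correction, an
  allele-permutation panmixia test, PCA with top-F_ST subsetting,
  paired-locus F_ST correlation, an LD screen and Fisher's combined
  probability test.

The methods vignette (`vignettes/rsta-methods.Rmd`) documents the model,
every tunable parameter, and the design decisions behind the simulator's
calibration.

## Worked example

Simulate the default study design — 2 populations × 10 diploid
individuals, 2,000 cut-site loci, 24% polymorphic — run the calling
pipeline, and analyze the genotype matrix:

```r
library(rsta)

spec <- population_spec(n_loci = 2000, fst_sim = 0.003, seed = 821)
ds   <- simulate_dataset(spec)                 # scans + known truth
res  <- rsta_pipeline(ds$scans_raw, ds$manifest, seed = 822)
ev   <- evaluate_pipeline(res, ds$truth)

round(100 * ev$concordance, 2)   # genotype concordance vs truth
#> [1] 99.66
round(100 * ev$sensitivity, 2)   # polymorphic loci recovered
#> [1] 99.79

af  <- allele_frequencies(res$geno, ds$truth$populations)
tab <- fst_table(af$p, af$n_called)
ps  <- permute_panmixia(res$geno, ds$truth$populations,
                        n_permutations = 1000, seed = 7)
ps$rank_observed_mean   # rank of observed mean F_ST among permutations
```

99.66% of genotype calls at loci flagged polymorphic match the simulated
truth (the paper-derived thresholds are used untouched), 99.8% of loci
polymorphic among the sampled individuals are recovered, and the
permutation rank quantifies how far the observed F_ST distribution sits
above its panmixia null. A command-line front end (`exec/rsta`) wraps
the same functions as `rsta design / simulate / call / popgen`
subcommands.

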