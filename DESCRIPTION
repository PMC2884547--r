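Package: rsta
Title: Restriction Site Tiling Analysis for Polymorphism Discovery and
    Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale implementation of Restriction Site Tiling Analysis
    (RSTA), a genome-scanning method that discovers and genotypes
    restriction-site polymorphisms by comparative two-channel hybridization
    of digested and non-digested genomic DNA to cut-site-centered array
    probes. Provides array tile design from a genome FASTA (recognition-site
    scanning, uniqueness screening, control and degradation-series tiles),
    a physics-based hybridization simulator for diploid individuals from
    structured populations, per-locus signal aggregation with quality
    control, polymorphism identification by univariate Gaussian mixture
    clustering with BIC model selection, fixed-threshold genotype and indel
    calling, and downstream population genetics: allele frequencies,
    heterozygosity, per-locus F_ST, Hardy-Weinberg tests with
    Benjamini-Hochberg correction, an allele-permutation panmixia test,
    PCA, paired-locus F_ST correlation, a linkage-disequilibrium screen and
    Fisher's combined probability test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    mclust,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
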