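Package: introscan
Title: Introgression Scans and Population-Genomic Summaries for
    Resequenced Crop Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genomic analysis of biallelic SNP cohorts,
    oriented at detecting hulled-to-naked oat introgression but applicable
    to any diploid resequencing panel.  Implements genotype-quality masking
    and hard site filtering, sliding-window nucleotide diversity and
    Weir-Cockerham Fst, pairwise identity-by-state distances, runs of
    homozygosity, linkage-disequilibrium decay profiles, Patterson's D
    with a weighted block jackknife, a relative identity-by-descent (rIBD)
    windowed introgression scan with z-score segment calling,
    fourfold-degenerate site extraction with a calibration-ratio divergence
    clock, and candidate-gene haplotype grouping with phenotype contrasts.
    A founder-mosaic cohort simulator with recorded ancestry tracts, true
    IBD segments and planted phenotype effects provides ground truth for
    every scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
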