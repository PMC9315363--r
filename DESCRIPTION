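Package: eigensel
Title: Genetic Diversity and EigenGWAS Selection-Signature Scans for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for population-genomic analysis of
    selfing crop diversity panels genotyped with biallelic SNPs (e.g.
    genotyping-by-sequencing in hexaploid wheat). Reads multi-sample VCF plus
    sample metadata into a dosage-matrix backbone, applies standard marker QC
    (missingness, minor allele frequency, heterozygosity, unmapped markers),
    and computes per-marker diversity statistics (MAF, observed
    heterozygosity, Nei gene diversity, polymorphism information content,
    transition/transversion accounting), sliding-window nucleotide diversity
    and Tajima's D, VanRaden kinship, standardized genomic relationships,
    PCA, Rogers' distance and neighbor-joining trees, Weir-Cockerham per-SNP
    and pairwise FST, three-level AMOVA with permutation tests, Hill-Weir
    linkage-disequilibrium decay fitting, and an EigenGWAS selection scan
    with genomic control, permutation thresholds, and 5-Mb region merging.
    Includes a Balding-Nichols genotype simulator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
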