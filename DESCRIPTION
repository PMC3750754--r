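Package: rohscan
Title: Runs of Homozygosity, Variant Consequences, and Genotype
    Concordance for Multi-Breed Resequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting runs of homozygosity (ROHs) from dense
    diploid genotype data by fixed-width binning of the per-bin
    homozygosity degree, moving-average smoothing, and thresholding;
    breed-specific and cross-platform ROH set algebra; variant
    consequence annotation (synonymous, missense, nonsense, readthrough,
    splice-site, frameshift and in-frame indels) against transcript
    models; NS/SS/I filtering with novelty, deleteriousness, and
    breed-specificity rules; consensus SNP-array genotyping; and
    chip-versus-sequencing genotype concordance metrics (overall
    concordance, non-reference sensitivity and discrepancy). Includes a
    synthetic-data generator that plants homozygous tracts in multi-breed
    diploid callsets with a paired SNP-array mirror, providing ground
    truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
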