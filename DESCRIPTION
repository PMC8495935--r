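Package: svpopgen
Title: Population Genetics of Structural Variants in Crop Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for population-level structural-variant (SV)
    panels: depth-masked reading of multi-sample SV VCFs, a staged quality
    filter cascade (paired-end support, breakpoint precision, size, missing
    data, minor allele frequency), site frequency spectra with Watterson's
    theta and a neutral 1/i expectation, windowed nucleotide diversity,
    linkage-disequilibrium decay profiles with half-decay distances,
    SNP-based k-means population structure selected by average silhouette
    width, and a permutation-backed test for deletions specific to a single
    population cluster. Includes a synthetic panel generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
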