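Package: popdiv
Title: Diversity Measures for Collections of Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the genetic diversity of a collection of populations from
    biallelic SNP allele-frequency data. Implements four approaches -- pooling,
    averaging, pairwise differencing, and fixing -- that extend two
    single-population diversity measures, expected heterozygosity and split
    system diversity, to sets of populations. Includes VCF ingestion with
    minority-allele presence/absence encoding, brute-force maximum-diversity
    subset search with complete tie reporting, inter-measure Pearson
    correlation analysis with standard errors, and seeded synthetic
    allele-frequency generators for randomization experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
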