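Package: polypanel
Title: Dosage Genotyping and Diversity Analysis for Autotetraploid SNP-Array Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts normalized two-channel SNP-array intensities (theta
    values) into diploid and allele-dosage genotype calls for autotetraploid
    crops such as cultivated potato, using per-marker cluster boundaries
    anchored by parental genotypes and expected F1 segregation ratios.
    Provides marker quality-control filters (missing-data and multi-mapping
    removal), per-line heterozygosity and allele-dosage frequency spectra
    with subsampling corrections, Rogers genetic distances with UPGMA
    clustering, chi-square allele- and genotype-frequency enrichment tests
    between market classes with random-marker baselines, and a synthetic
    panel generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
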