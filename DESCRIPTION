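Package: biallele
Title: Biallelic Expression Calling for Imprinted and X-Linked Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects biallelic expression of imprinted and X/Y-linked genes
    from per-SNV allele counts produced by RNA-seq allele-specific expression
    counters, in bulk and single-cell data. Classifies SNVs as biallelic,
    monoallelic or low-coverage using overall-depth, minor-allele-count and
    allelic-ratio (or exact binomial) filters, collapses calls to gene-level
    status, aggregates single-cell calls into per-group biallelic fractions,
    computes X-inactivation metrics (average allelic ratio, escapee
    detection), benchmarks calls against exome-derived heterozygous genotypes
    (false discovery rate) and validated truth sets (precision/recall grids),
    and simulates allele-count tables with known imprinting and
    X-inactivation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    parallel,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
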