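Package: eqtlscan
Title: Region-Based eQTL Scans of SNP Genotypes Against Transcript Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates SNP genotypes in a genomic region (or an explicit SNP
    list, possibly in trans) with normalized expression levels of a gene's
    transcript probes. Reads PLINK-text genotype files (PED/MAP) and
    tab-delimited probe-by-sample expression tables, codes genotypes under
    additive, dominant, recessive or genotypic models, fits per-SNP linear
    regressions with Wald/F tests, adjusts p-values by Bonferroni, Holm,
    Sidak, Benjamini-Hochberg and Benjamini-Yekutieli procedures, and writes
    UCSC Genome Browser custom tracks plus tab-delimited result tables. A
    synthetic-data module generates HapMap-structured fixtures (four
    populations, trio pedigrees, Hardy-Weinberg founders, Mendelian
    transmission) with known ground truth for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
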