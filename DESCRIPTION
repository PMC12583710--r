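Package: sitefx
Title: Cross-Context Variant Effect Scoring on Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the predicted effect of non-coding SNPs on chromatin
    accessibility under a pluggable sequence-to-profile predictor, assesses
    significance against a dinucleotide-preserving shuffle empirical null,
    detects variants whose effects deviate between two cellular contexts
    (e.g. ascending versus descending aortic cell types) via regression and
    externally studentized residuals, exports their flanking windows for
    motif discovery, and tests GWAS nearest-gene sets for enrichment among
    differentially expressed genes. Ships a synthetic-data module that
    generates genomes with planted context-specific motifs, variant lists,
    correlated two-context effect-size matrices with injected deviants,
    differential-expression tables, and single-cell ATAC fragment files with
    known ground truth, plus pseudobulk fragment-to-tagAlign preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
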