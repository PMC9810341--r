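Package: chromprime
Title: Chromatin Priming Analysis from Pseudobulk Multi-Ome Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying epigenomic priming of gene programs from
    pseudobulk chromatin-accessibility and expression counts. Implements
    RPKM-style promoter activity scoring with data-driven promoter-length
    selection, joint expression/accessibility gene typing into priming
    classes (Type1a/1b, Type2a/2b, Type3, Type4), pseudocount fold-change
    and z-score promoter-mark enrichment with Benjamini-Hochberg
    correction, SNP-in-open-chromatin enrichment against width-preserving
    shuffle nulls, and a simplified activity-by-contact enhancer-gene
    linking score. Ships a synthetic multi-ome generator with planted
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
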