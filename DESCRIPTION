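Package: epimapr
Title: Sort-Seq Epitope Mapping from Yeast-Display Selections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for yeast surface display epitope mapping by
    sort-seq. Simulates error-prone PCR mutagenized antigen libraries and
    FACS selection of loss-of-binding clones, maps fragment sequencing reads
    to the reference ORF with codon-aware amino-acid mutation counting,
    normalizes per-position mutation frequencies across libraries by the
    median of geometric mean ratios, calls candidate epitope positions at a
    log2 enrichment threshold relative to the within-sample median, and
    filters called positions that are buried or disulfide-bonded in an
    atomic structure or precomputed residue annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
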