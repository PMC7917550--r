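Package: pirnaterm
Title: Transcription Termination Analysis at piRNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and length analysis of short-capped piRNA
    precursors, weighted-bootstrap localization of promoter-proximal RNA
    polymerase II pause peaks, detection of Integrator cleavage fragments in
    5'-monophosphate small RNA libraries, termination-signal scoring, and
    CAGE-based readthrough quantification for C. elegans piRNA (21U-RNA)
    loci. Includes a synthetic-data generator implementing the two-pause /
    endonucleolytic-cleavage model of piRNA transcription termination, so
    that every analysis stage can be exercised end-to-end without external
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
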