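Package: twintx
Title: Cross-Species De Novo Transcriptome Comparison and QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing de novo transcriptome assemblies of two
    closely related species: read demultiplexing and cleaning (adapter,
    barcode, length, N-content and rRNA filters), homopolymer run-length
    profiling, a seeded local-alignment search emitting standard 12-column
    tabular hits, best-hit category filtering, Ortholog Hit Ratio (OHR)
    completeness assessment, reciprocal-best-hit ortholog calling with
    identity statistics, species-specific (PDEG) set extraction, ORF-based
    CDS completeness classification, and Fisher exact GO-term enrichment
    with FDR correction. Includes a twin-transcriptome simulator with
    known orthology, divergence, coverage fractions and read structure,
    used as ground truth throughout the test suite, and a pipeline driver
    that runs the full analysis from one configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
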