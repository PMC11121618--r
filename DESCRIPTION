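Package: g4context
Title: G-Quadruplex Sequence Context around Somatic Mutation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of G-quadruplex (G4) forming sequence context around
    somatic mutation sites in tumour exomes. Detects weak and strong G4 motifs
    with strand-symmetric regular-expression patterns, extracts +/-70 nt
    windows around variants with germline haplotype editing, tests per-sample
    enrichment of G4 context against a capture-panel-matched random null
    (chi-square and two-proportion z-tests, Wilson score intervals), stratifies
    mutation spectra by G4 category, predicts G4 gain/loss under somatic
    mutations, and discovers group-exclusive germline SNPs under a population
    allele-frequency filter. Includes a fully synthetic study generator
    (reference with planted motifs, panel BED, somatic and germline VCFs) so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
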