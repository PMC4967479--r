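Package: ambicode
Title: Ambiguous Genetic Codes and Context-Dependent Translation Termination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers nuclear genetic codes from profile-alignment evidence
    (codon/consensus amino-acid count matrices with per-codon calling and
    sequence-logo export), analyses poly(A)-anchored transcript ends
    (poly(A)-tail detection, primary-stop calls in the terminal window,
    3' UTR length distributions, positional codon counts toward the
    poly(A) site and a stop-codon depletion test), quantifies translation
    termination and stop-codon readthrough from ribosome-profiling
    footprints, and provides small molecular-evolution utilities
    (Nei-Gojobori dN/dS, stop-codon usage, fourfold-degenerate-site
    composition). A synthetic-data generator emulates transcriptomes with
    reassigned or ambiguous stop codons, AU-rich short 3' UTRs, poly(A)
    tails and ribosome-protected fragments so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
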