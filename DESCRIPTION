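Package: codonsmith
Title: Rare-Codon Identification and Synonymous Codon Optimization of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies rare (< 10 per thousand) and highly rare (<= 5 per
    thousand) codons in a coding DNA sequence against any user-supplied codon
    usage table in the Codon Usage Database (Kazusa) text layouts, and
    optimizes the sequence by three strategies: one-click replacement of every
    rare codon with its most frequent synonym, bulk per-codon-type
    substitution, and individual codon-by-codon edits. Every strategy
    guarantees the encoded protein is unchanged. Also computes base
    composition (G+C / A+T content), verifies original-versus-optimized
    protein identity, and scans both strands for restriction-enzyme
    recognition sites (IUPAC ambiguity codes supported) against a bundled
    catalogue of common commercial enzymes. Ships a seeded random-fixture
    generator, plain-text and HTML report renderers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
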