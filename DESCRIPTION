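Package: paircons
Title: Position-Specific Codon and Codon-Pair Conservation in Orthologous
    Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies position-specific conservation of codons and adjacent
    codon pairs across orthologous open reading frames of closely related
    yeasts. Builds codon-aware alignments by translating coding sequences
    (standard or alternative yeast nuclear genetic code), aligning the amino
    acid sequences and back-translating; computes per-codon and per-pair
    conservation rates against a reference species; identifies codon pairs
    conserved in excess of their constituent codons with an origin-constrained
    linear fit and sigma-outlier calls; scores pairs with pseudocounted
    normalized conservation scores and dipeptide-family z-scores; provides
    reading-frame-shift and within-ORF positional controls, enrichment
    statistics, and gene-property comparisons; and ships a synthetic ortholog
    generator with planted conserved codon pairs so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
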