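Package: txcurate
Title: ORF-Evidence Curation of De Novo Assembled Transcriptomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly quality control for de novo assembled
    transcriptomes. Extracts six-frame stop-to-stop open reading frames,
    uses tabular protein-homology evidence to partition transcripts into
    uniquely annotated, unannotated, broken-ORF, long-repeat and
    multi-gene (chimera-candidate) classes, merges fragmented transcript
    pairs via unique non-repetitive terminal anchors, expands gene
    families iteratively from a seed protein, normalizes raw read counts
    by transcript length, and profiles amino-acid composition of
    representative ORFs. Includes a seeded synthetic-transcriptome
    generator with ground-truth labels and internally consistent mock hit
    tables so the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
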