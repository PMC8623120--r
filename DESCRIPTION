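Package: msarefine
Title: Post-Alignment Evaluation and Refinement of Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates multiple sequence alignments with three post-alignment
    criteria - the sum-of-pairs score (SPS, optionally pair-weighted), the
    pairwise alignment inconsistency index (PAI), and the position weight
    matrix differential (PWMD) - and automatically repairs the residue
    placement errors that progressive aligners leave behind. Candidate
    repairs are shifts of contiguous residue blocks across adjacent gap
    runs, optionally constrained to codon triplets, searched greedily until
    no shift improves the chosen criterion. Includes an internal global
    pairwise aligner (Needleman-Wunsch/Gotoh) for PAI, aligned-FASTA and
    NCBI score-matrix input, and seeded synthetic-alignment generators that
    emulate the published worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
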