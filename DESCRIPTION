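Package: novelpep
Title: Proteogenomic Discovery of Novel Peptides from Assembled Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds six-frame-translated, longest-ORF custom protein search
    databases from de novo assembled transcripts merged with a labelled
    reference proteome and reversed decoys; identifies novel peptides from
    external search-engine output (reference substring matching with I/L
    folding, PSM aggregation, PepQuery result filtering); projects peptides
    to genomic coordinates through transcript alignments and classifies
    them into splice, UTR, noncoding-gene and novel-ORF event categories
    against a genome annotation; and screens peptide regions for survival
    association with Kaplan-Meier curves and log-rank tests, controlled by
    the parent gene. A fully synthetic fixture generator produces a toy
    genome with engineered events, PSM tables and clinical cohorts so the
    entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'annotation.R'
    'bed.R'
    'classify.R'
    'clinical.R'
    'database.R'
    'digest.R'
    'translate.R'
    'fixtures.R'
    'novelpep-package.R'
    'novelty.R'
    'pipeline.R'
    'project.R'
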