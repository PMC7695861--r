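Package: beditkit
Title: Analysis Toolkit for Cas-Embedded Base-Editor Screens and Off-Target Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the computational stages of a transposon-based
    Cas9 deaminase-embedding screen and its off-target follow-up as a tested,
    reusable pipeline: insertion-site mapping on a circular plasmid from
    soft-clipped read alignments, codon-consequence logic for a premature-stop
    selection marker, amplicon deep-sequencing quantification of base editing
    and indels with quality-filtered pileups, transcriptome edit filtering,
    three-caller consensus SNV calling against a paired control,
    substitution-class summaries, and protospacer-mismatch off-target site
    scanning with PAM constraints. A seeded synthetic-data generator produces
    every input format the pipeline consumes together with ground truth, so
    each stage is scored against known simulated signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
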