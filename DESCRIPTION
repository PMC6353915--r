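Package: paleomito
Title: Authentication, Decontamination and Dating of Ancient Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and dating a mitochondrial genome from
    heavily contaminated ancient-DNA sequencing libraries. Implements terminal
    C-to-T deamination profiling (unconditional and conditional), duplicate
    fusing and length filtering, damage-restricted consensus calling with
    heteroplasmy flagging, present-day contamination estimation from
    diagnostic positions, a Poisson molecular clock on private substitutions,
    and radiocarbon quality-control arithmetic with calibration-curve mapping
    to highest-posterior-density calendar ranges. A synthetic-data module
    generates labelled fragment mixtures (endogenous molecules with
    terminal-decaying damage plus present-day contaminants) so every stage of
    the pipeline can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
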