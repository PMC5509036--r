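Package: mirtail
Title: Classification and Quantification of miRNA Length Isoforms and 3'
    Nontemplated Additions from Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hairpin-anchored classification of small RNA reads into
    templated microRNA length isoforms (isomiRs) and 3' nontemplated
    nucleotide additions (tailing, e.g. mono-uridylation and
    mono-adenylation), with adapter trimming, spike-in normalisation,
    per-length isoform spectra, per-position tail nucleotide composition,
    a terminal-versus-internal mismatch fold statistic for artefact
    exclusion, and a fully ground-truthed synthetic small RNA library
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
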