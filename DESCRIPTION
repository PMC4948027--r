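Package: famevol
Title: Gene Family Evolution Analysis for Plant Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the desk analysis of a plant gene family, built around
    the heat shock transcription factor (Hsf) family of desert poplar: protein
    physicochemical profiling (molecular weight, isoelectric point, charged
    residue fractions, instability index, aliphatic index, GRAVY), Hsf
    functional-motif scanning and class A/B/C assignment from domain geometry,
    Nei-Gojobori Ka/Ks estimation with Jukes-Cantor correction, sliding-window
    selection scans and synonymous-clock divergence dating, microsynteny
    duplicated-block detection with tandem/WGD/dispersed duplication typing,
    promoter cis-element scanning against an IUPAC catalog with an enrichment
    statistic, intron-phase annotation, and qRT-PCR differential-induction
    calling. Seed-deterministic synthetic-data generators with machine-readable
    ground truth make every stage testable without external genome resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
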