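Package: cleavemap
Title: Protease Cleavage-Site Specificity Profiling from Peptide
    Identifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles protease substrate specificity from shotgun-proteomics
    peptide identification lists. Reads Mascot XML exports or a plain
    tab-separated dialect, applies an Ion Score confidence filter, infers
    unique cleavage sites from peptide termini, extracts fixed P6-P5'
    residue windows in Schechter-Berger subsite coordinates, and builds
    position-specific count, frequency, background-normalized ratio and
    Z-score matrices. Includes P2-P1 pair and P3-P2-P1 triplet motif
    enrichment, conditional P1 distributions, unique-peptide length and
    missed-cleavage statistics, percent-difference sequence logos with
    binomial significance masking, heatmap rendering, and a probabilistic
    in-silico digestion simulator that generates ground-truthed
    identification tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    grid,
    jsonlite,
    methods,
    pheatmap,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
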