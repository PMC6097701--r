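Package: erescape
Title: Scoring and Simulation of ER-ESCAPE Tripeptide Motifs for Surf4/Erv29p
    Cargo Receptor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the amino-terminal tripeptide (ER-ESCAPE) motif that
    determines binding of soluble secretory cargo to the ER cargo receptor
    Surf4 (Erv29p in yeast). Provides a per-position amino-acid contribution
    model with additive tripeptide scoring and affinity classification,
    extraction of mature-protein starting tripeptides from FASTA plus
    signal-peptide cleavage annotations, survey tallies over tripeptide
    tables, isotonic calibration of motif score against normalized
    steady-state cargo levels, single-site saturation binding fits for
    microsome titration data, a deterministic mass-action model of
    receptor-limited prioritization of ER exit, global pairwise protein
    alignment with affine gaps, and seeded synthetic-data generators so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, MotifAnnotation, Classification, Regression
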