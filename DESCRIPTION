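Package: kodepletion
Title: Knockout-Depletion Analysis of Essential Protein Overabundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for knockout-depletion experiments in
    naturally competent bacteria, in which an essential gene is replaced by a
    resistance cassette and the pre-existing protein pool is diluted by
    growth until function fails.  Simulates protein-dilution dynamics at
    single-cell (microcolony lineage) and library (transposon-insertion
    sequencing) scale, reconstructs the fitness landscape and protein
    overabundance from dilution trajectories, classifies genome-wide
    depletion trajectories into no-effect, sufficiency, and overabundance
    classes by nested likelihood-ratio tests, and compares measured
    overabundance against the robustness-load trade-off (RLTO) optimality
    prediction as a function of transcription level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
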