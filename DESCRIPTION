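Package: trgpipe
Title: Profile-HMM Discovery and Classification of Translational GTPase
    Subfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An iterative profile hidden Markov model pipeline for
    discovering and classifying translational GTPase (trGTPase)
    subfamilies across proteomes. Provides an in-package profile-HMM
    engine (Viterbi and forward scoring in compiled code, Gumbel
    E-value calibration, sequence sampling), candidate gathering and
    sequence-hygiene stages (G-domain membership checks, analysis-region
    extraction, gap-column filtering, fusion flagging, active-site
    surveys), neighbor-joining clade delineation with bootstrap support,
    competitive subfamily assignment with taxonomy-aware dual notation
    and iterative model refinement, a machine-readable registry of the
    57-subfamily trGTPase classification with its evolutionary timeline,
    and a seeded synthetic-proteome generator that makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
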