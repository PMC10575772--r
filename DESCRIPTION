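Package: adaptsurf
Title: Adaptive-Behaviour Outcome Subgroups and Cortical Surface Neuroanatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links longitudinal adaptive-behaviour outcome subgroups in autism
    to cortical-surface neuroanatomy and to gene-expression correlates.
    Provides minimal-clinically-important-difference (MCID) outcome
    classification from Vineland Adaptive Behaviour Scale change scores,
    vertex-wise general linear models of surface area and cortical thickness
    at baseline, follow-up and as longitudinal change, random-field-theory
    cluster correction for non-isotropic t-fields on triangulated surfaces,
    spatial transcriptomic decoding with spin-test inference, and Fisher
    odds-ratio gene-set enrichment with Benjamini-Hochberg correction.
    Includes a seeded synthetic cohort generator (phenotypes, two-timepoint
    vertex maps, expression atlas, gene sets) emulating the statistical
    structure of a longitudinal autism cohort, so the full pipeline is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
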