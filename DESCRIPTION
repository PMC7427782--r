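Package: helixstates
Title: Geometry of Closed and Open Helix Conformations in Receptor Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the conformational states of transmembrane
    helices in crystallographic models of membrane receptors, built around the
    closed/open interconversion of the adiponectin receptor AdipoR1. Provides
    main-chain hydrogen-bond geometry with amide hydrogen rebuilding and
    3(10)- versus alpha-helical classification, backbone dihedrals, helix-axis
    and bend-angle estimation, the helical advance metric, Kabsch
    superposition with per-atom displacement analysis, alternate-location
    (dual-conformer) splitting with occupancy bookkeeping, and a synthetic
    backbone generator (ideal and kinked helices, dual-conformer and
    metal-site models) that supplies ground-truth geometry for testing every
    analysis stage without any structure download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
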