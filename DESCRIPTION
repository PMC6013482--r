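Package: tetraconf
Title: Integrative Analysis of a Monomer-to-Tetramer Conformational Switch
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize a two-domain protein's monomer-to-tetramer
    conformational switch by integrating orthogonal structural and biophysical
    measurements: elastic-network normal-mode analysis with eigenvector
    tracking of domain closure, crosslinking mass-spectrometry distance
    restraint mapping, per-residue hydrogen-deuterium exchange differential
    profiling, small-angle X-ray scattering analysis (Guinier, P(r),
    C4-symmetric rigid-body modelling), native mass-spectrometry charge-state
    deconvolution, thermal-shift Kd titration fitting, and sedimentation
    velocity c(s) distribution analysis. Seeded synthetic-data generators
    emulate every input so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
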