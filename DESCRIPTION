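Package: lipidbank
Title: Overlay-Databank Style Analysis of Lipid Bilayer Molecular Dynamics Simulations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for organising and analysing lipid-membrane molecular dynamics
    simulations in an overlay-databank layout: standardized simulation metadata
    (YAML entries, hash-derived identifiers, universal atom naming via mapping
    tables), calculators for basic membrane observables (C-H bond order
    parameters, electron density profiles and X-ray scattering form factors,
    area per lipid, bilayer thickness), PCA-based estimation of conformational
    sampling convergence, automatic quality evaluation and ranking against NMR
    order parameters and X-ray form factors, rare-event transport analyses
    (lipid flip-flops, water permeation and diffusion anisotropy), and a
    composition-to-property regression model. Seeded synthetic-fixture
    generators with analytically known ground truth exercise every component
    without external trajectory downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, yaml, jsonlite, signal, glmnet, bio3d
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
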