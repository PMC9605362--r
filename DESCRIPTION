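Package: outflowve
Title: Inverse Viscoelastic Finite-Element Analysis of Aqueous Outflow Tissues
Version: 0.1.0
Authors@R: person("Outflow", "Biomechanics Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates time-dependent (viscoelastic) shear moduli of the
    trabecular meshwork (TM), juxtacanalicular tissue (JCT), and Schlemm's
    canal (SC) inner wall from pressurization-driven boundary motion. The
    package provides a small explicit quasi-static finite-element solver with
    fully integrated 8-noded hexahedra, Hughes-Liu viscoelastic beam elements
    representing collagen fibrils, a mesh-free penalty beam-in-solid coupling,
    a synthetic-data generator that replaces unshared OCT recordings with
    forward-simulated boundary trajectories of known ground truth, bounded
    Nelder-Mead calibration stages with a perturbation-uniqueness audit, and
    one-way ANOVA / Scheffe reporting on fitted parameter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
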