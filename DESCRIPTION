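Package: angiomech
Title: Mechano-Sensitive Simulation of Tumour-Induced Angiogenesis and Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled multiscale in-silico model of vascular tumour growth: a
    three-dimensional hexahedral finite-element tissue continuum (explicit
    reaction-diffusion biochemistry for angiogenic factor, oxygen, matrix
    metalloproteinase and extracellular-matrix density; quasi-static
    hyperelastic mechanics with oxygen-driven multiplicative growth)
    dynamically coupled to a discrete one-dimensional capillary network with
    chemo-, hapto- and mechanotactic sprout guidance, stochastic branching,
    anastomosis, shear-stress-driven wall remodelling, and pressure-induced
    vessel compression and collapse.  Vascular, interstitial and
    transvascular flow are solved as one coupled quasi-steady linear system
    (Poiseuille, Darcy and Starling laws).  Includes morphometric analysis of
    the simulated networks (vascular density, inter-capillary distance,
    distance-map scaling parameters, perfusion classes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
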