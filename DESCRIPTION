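Package: osteomac
Title: Coupled Bone-Myeloid Population Dynamics of Bone Injury Repair
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled ordinary-differential-equation modelling of bone injury
    repair in the mouse tibia. Implements a nine-variable model of naive,
    pro- and anti-inflammatory monocyte/macrophage populations, osteoblasts,
    osteoclasts, bone volume and injury factors, an eighteen-member space of
    competing mechanistic hypotheses for osteoclast regulation, osteoblast
    expansion and macrophage polarization, homeostasis-constrained parameter
    derivation, weighted least-squares and Chebyshev fitting objectives with
    penalized Nelder-Mead multi-start estimation, AIC-based model ranking,
    replicate-level synthetic study-design data generation, and an in-silico
    oncostatin-M depletion perturbation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SystemsBiology, MathematicalBiology, TimeCourse, Software
RoxygenNote: 7.3.3
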