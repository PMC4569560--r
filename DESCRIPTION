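Package: adhesim
Title: Stochastic Adhesive Dynamics of Tumor Cell-Neutrophil Adhesion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Desk-scale stochastic simulator of the adhesive interaction
    between a circulating melanoma tumor cell and a substrate-adherent
    polymorphonuclear neutrophil (PMN). Receptor-ligand bonds between
    ICAM-1 on the tumor cell and the beta-2 integrins LFA-1 and Mac-1 on
    the PMN form and break stochastically with Bell-model
    distance-dependent rates evaluated locally on every pair of
    discretized membrane faces, act as Hookean springs, and are
    book-kept in a per-face, per-species molecule ledger with fractional
    molecule counts. A gated nonlinear-spring repulsion force keeps the
    cell surfaces apart, and the tumor cell moves with six degrees of
    freedom under an analytic near-wall shear-flow load surrogate
    (Stokes drag with wall corrections and shear-induced rotation) in
    place of a full CFD solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
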