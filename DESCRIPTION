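Package: cardioem
Title: Desk-Scale Coupled Cardiac Electromechanics with CRT and LVAD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled ventricular electromechanical simulation at desk scale:
    human ventricular cell electrophysiology (ten Tusscher-Noble-Noble-Panfilov
    2004 formulation), monodomain tissue propagation over an idealized
    biventricular geometry with Purkinje-network activation and bundle branch
    block, Rice-type cross-bridge myofilament mechanics with ATP economy, and a
    closed-loop lumped-parameter circulation with an optional continuous-flow
    left ventricular assist device. Provides electrical/mechanical activation
    timing maps (EAT, MAT, EMD), pressure-volume loop indices, cycle ATP
    consumption, and scenario comparisons for sinus rhythm, left and right
    bundle branch block, cardiac resynchronization therapy, and combined
    CRT + LVAD support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
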