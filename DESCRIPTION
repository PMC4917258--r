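Package: nram
Title: Ionic Model and Virtual Monolayers of Neonatal Rat Atrial Cardiomyocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An electrophysiological model of the neonatal rat atrial
    cardiomyocyte (NRAM) with a constitutively active acetylcholine-mediated
    potassium current (IKACh-c), together with a two-dimensional monodomain
    simulator of cultured monolayers. Provides Hodgkin-Huxley style ionic
    currents with two-compartment sarcoplasmic-reticulum calcium handling,
    single-cell pacing and restitution protocols, construction of virtual
    monolayers with random myofibroblast placement and intercellular
    conductance variability, spiral-wave initiation protocols (S1-S2
    cross-field and burst pacing), pharmacological block interventions, and
    analysis tools for activation maps, conduction velocity, action-potential
    duration maps, spiral-tip trajectories and dominant frequency.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
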