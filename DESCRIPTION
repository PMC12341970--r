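Package: gapres
Title: Frequency-Dependent Electrical Coupling and Membrane Resonance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing subthreshold membrane resonance and the
    frequency dependence of gap-junction electrical coupling in small
    oscillatory circuits such as the crustacean pyloric pacemaker.
    Generates exponential-chirp (ZAP) stimulus protocols, estimates
    impedance, coupling-coefficient and coupling-conductance frequency
    profiles from dual-recording traces with sixth-degree polynomial
    resonance fits, provides closed-form impedance theory for electrically
    coupled linear resonator neurons, conductance-based single-compartment
    and ball-and-stick cable models run under current or ideal voltage
    clamp, and a two-compartment bursting-pair model used to quantify how
    a frequency-dependent coupling conductance shapes burst synchrony.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
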