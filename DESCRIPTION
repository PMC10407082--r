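Package: suctionsim
Title: Simulation and Detection of Ventricular Suction During Rotary
    Blood Pump Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A software test bench for studying suction events in
    patients supported by a continuous-flow left ventricular assist
    device (LVAD). Couples a closed-loop lumped-parameter model of the
    cardiovascular system (time-varying elastance chambers, diode
    valves, systemic and pulmonary vascular beds) to an HVAD-like
    rotary pump model and a collapsible-apex inflow module that
    engages when left ventricular pressure falls below 0 mmHg.
    Includes calibrated dilated and restrictive cardiomyopathy
    profiles, hypovolemia-ramp and speed-sweep protocols, a beat-level
    suction detection pipeline (beat segmentation from 50-Hz estimated
    pump flow, three suction features, a 3-split decision tree), and
    validation tooling (confusion statistics, feature distribution
    summaries, normality and distribution-comparison tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
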