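Package: aequosim
Title: Digital Twin of a Silicon-Photomultiplier Aequorin Luminometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an aequorin bioluminescence luminometer built around a
    silicon photomultiplier (SiPM) read out in parallel by a single-photon
    counting (SPC) chain and a gated charge-integration (CI) chain. Provides
    parametric calcium scenarios with aequorin consumption kinetics,
    stochastic photon/dark-count arrival simulation with paralyzable or
    non-paralyzable dead time, QDC-style gated charge acquisition with block
    averaging, and the characterization pipeline used to qualify such
    instruments: log-log response-linearity fits, analytic and empirical
    limits of detection, peak-rate recovery, and agonist/lysis
    discharge-ratio statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: Rcpp, stats, utils, withr, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
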