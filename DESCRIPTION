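Package: pulsesync
Title: Synchrony and the Downstream Effectiveness of Excitatory Input
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for studying whether tighter
    synchrony of an excitatory input volley makes it more effective at
    driving a downstream neuron. Implements linear integrate-and-fire,
    theta (quadratic integrate-and-fire), Wang-Buzsaki, and reduced
    Traub-Miles target models under charge-preserving compressed current
    pulses and periodic pulse trains; the efficiency metrics that separate
    input-until-threshold from input-until-firing accounting (peak response,
    critical compression, firing time and ratio, charge-to-fire, and pulse
    counts); closed-form results for the integrate-and-fire neuron; and an
    all-to-all excitatory-inhibitory network producing a
    pyramidal-interneuronal gamma (PING) rhythm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
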