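Package: negimage
Title: Negative-Image Learning and Contrast-Invariant Cancellation in an
    Electrosensory Feedback Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of a cerebellar-like circuit in the electrosensory
    lateral-line lobe of weakly electric fish that cancels redundant global
    amplitude modulations. A bursting leaky integrate-and-fire pyramidal
    neuron with a depolarizing-after-potential mechanism receives saturating
    electroreceptor (P-unit) input and phase-delayed parallel-fiber feedback;
    burst-timing-dependent depression together with slow homeostatic
    potentiation shapes the feedback weights into a negative image of the
    stimulus, yielding contrast-invariant cancellation. Includes calibration
    routines, cancellation and degradation metrics, a synthetic reference
    generator, and experiment drivers for cancellation grids and scans over
    the learning contrast and the potentiation time constant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE, load = "source")
RoxygenNote: 7.3.3
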