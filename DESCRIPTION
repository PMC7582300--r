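Package: ppgectopy
Title: Ectopic Beat and Atrial Fibrillation Discrimination from Pulse Intervals
Version: 0.1.0
Authors@R:
    person("PPG", "Rhythm Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects premature atrial and ventricular contractions (PAC/PVC)
    and discriminates them from atrial fibrillation (AF) and normal sinus
    rhythm (NSR) in 30-second windows of beat-to-beat heart-rate data derived
    from photoplethysmography (PPG). The method maps successive heart-rate
    differences onto a nine-quadrant Poincare plot, mines the quadrant
    trajectory for the repeating 'kite' patterns characteristic of periodic
    ectopy (bigeminy, trigeminy, quadrigeminy), and applies vector-resemblance
    decision rules based on the dispersion of trajectory vector angles.
    Includes a synthetic rhythm generator, a simple pulse-peak detector, and
    an evaluation harness (confusion matrices, sensitivity/specificity/PPV/
    NPV/accuracy, threshold sweeps) so the method is fully testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
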