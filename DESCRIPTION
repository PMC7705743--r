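Package: boatools
Title: Bio-Opto-Acoustic Otolith Stimulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis tools for Bio-Opto-Acoustic (BOA) experiments, in which
    rapidly oscillated optical traps vibrate individual otoliths of larval
    zebrafish to simulate sound at a single hearing organ.  Provides a damped,
    stiffness-bound oscillator model of otolith motion with least-squares
    fitting of drag and stiffness from amplitude-frequency data; subpixel
    cross-correlation registration of high-speed otolith videos with
    spectrogram-based vibration amplitude estimation; a regression and
    cityblock k-means pipeline for brain-wide calcium traces, including
    GCaMP regressor construction, cluster selection criteria, per-trial peak
    responses and super-additivity indices; and synthetic-data generators
    (otolith videos, displacement traces, multi-fish calcium datasets with
    planted cluster structure) so the whole pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
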