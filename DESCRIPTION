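Package: eitresp
Title: Portable Electrical Impedance Tomography Respiratory Monitoring Toolkit
Version: 0.1.0
Authors@R:
    person("EIT", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Complete signal-processing chain for a portable 16-electrode
    electrical impedance tomography (EIT) respiratory monitor: the modified
    Sheffield adjacent stimulation/measurement protocol and its raw-data
    codec, a finite-element forward simulator on a breathing thorax phantom
    with an analog-chain emulator, carrier-burst demodulation to peak-to-peak
    voltage matrices, flow-to-volume integration with drift removal, breath
    detection and instantaneous respiratory rate, per-subject tidal-volume
    regression, nonparametric Bland-Altman agreement statistics, and
    linearized difference-image reconstruction with pixel-level respiratory
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
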