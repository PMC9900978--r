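Package: voltim
Title: Simulation and Analysis of Scanless Two-Photon Voltage Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing scanless two-photon
    voltage-imaging experiments with sculpted, temporally focused light.
    Implements Fourier-optics synthesis of soma-sized excitation spots
    (generalized phase contrast, low-NA Gaussian, Gerchberg-Saxton
    computer-generated holography, weighted multi-spot holography),
    angular-spectrum propagation with a spectral temporal-focusing model,
    a forward model for camera movies of membrane-localised genetically
    encoded voltage indicators (shot noise, photobleaching with dark-interval
    recovery, strobed illumination, optogenetic actuation), and the matching
    analysis pipeline: segmentation, regression-based pixel weighting, trace
    detrending, template-matching spike detection, trial averaging, and
    figure-of-merit metrics (SNR, photostability, photorecovery,
    power-response fits, resolution curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
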