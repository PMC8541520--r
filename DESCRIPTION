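Package: gelimetry
Title: Camera Linearity and Gel Densitometry Evaluation for Gel-Document Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates the radiometric linearity of cameras used in gel-document
    (electrophoresis imaging) systems and the sensitivity of the resulting gel
    photographs. Brightness-gradient test images taken under PWM-controlled LED
    illumination are reduced to normalized intensity profiles, fitted with
    polynomials scored by the population variance of the residuals, and compared
    across brightness levels either against proportionally scaled reference fits
    or through per-level optimal scaling constants whose deviation from the
    PWM/100 baseline summarizes camera linearity. Gel photographs are perspective
    rectified, band volumes are quantified by background-subtracted densitometry,
    and a dilution series is regressed to obtain R-squared and the derived
    signal-to-noise ratio, including an alternating-shot rank comparison between
    cameras. A seeded synthetic camera and gel simulator with known ground truth
    stands in for the imaging hardware so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
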