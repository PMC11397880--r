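Package: tirsurvey
Title: Design and Analysis of Thermal-Infrared Drone Surveys of Arboreal Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing thermal-infrared (TIR) drone
    surveys of arboreal primates. Provides closed-form oblique-camera
    ground-projection geometry (footprints, ground sample distance,
    area-equalisation masking, pixel-size detection limits), factorial
    flight-design expansion with frame-subsampling speed simulation, a
    synthetic survey and multi-coder generator, Poisson random-intercept
    count models fitted by adaptive Gauss-Hermite quadrature with
    likelihood-ratio tests, and Fleiss' kappa inter-coder agreement
    summaries with Landis-Koch bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
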