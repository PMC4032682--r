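Package: avscreen
Title: Doppler Hemodynamics and Color Relation Classification for
    Arteriovenous Access Stenosis Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Screens hemodialysis arteriovenous access stenosis from
    multiple-site Doppler ultrasound velocimetry.  Peak-systolic and
    peak-diastolic velocities measured at the arterial anastomosis, loop
    and venous anastomosis sites are converted into dimensionless
    hemodynamic numbers (Reynolds, Womersley, Strouhal, critical peak
    Reynolds, supracritical Reynolds, resistive index) and assembled into
    six-feature per-unit patterns.  A color relation analysis classifier
    maps pattern similarity grades through an HSV-style transform to a
    hue-angle decision; its recognition coefficient is tuned by particle
    swarm optimization with time-varying acceleration coefficients.  A
    synthetic cohort generator with published class-conditional velocity
    statistics makes the whole pipeline trainable and testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
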