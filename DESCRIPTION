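Package: sagplan
Title: Radiograph-Based Sagittal-Plane Planning for Total Knee Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational geometry for preoperative sagittal-plane planning of
    total knee arthroplasty from lateral radiograph silhouettes. Constructs the
    femoral intramedullary guide line from the anterior cortex and the implant's
    anterior flange angle, computes the femoral entry distance (FED), builds the
    tibial extramedullary guide line from the fibular shaft axis with a planning
    slope angle (PSA), and validates planned against executed resections via
    gamma and delta angles and a +/-2 degree target range. Includes a parametric
    generator of lateral femur and lower-leg silhouettes with controllable
    bowing, slope and soft tissue, radiographic bowing morphometry, a
    Monte-Carlo surgical execution-error simulator, and a cohort-level
    statistical harness (paired comparisons with normality screening, multiple
    regression on absolute angle differences, paired-t sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
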