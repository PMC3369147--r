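Package: hipcov
Title: Three-Dimensional Femoral Head Coverage and Radiographic Measures
    of Acetabular Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies acetabular coverage of the femoral head from
    triangulated surface models of the proximal femur and an ordered
    acetabular rim curve: periodic-spline rim fitting and projection onto
    the head surface, principal-curvature detection of the head-neck
    junction, partition of the head into anterolateral, anteromedial,
    posterolateral and posteromedial regions, and percent coverage per
    region.  Also computes the six standard measures of acetabular
    morphology from anteroposterior-radiograph landmarks (extrusion
    index, crossover ratio, acetabular angle, acetabular index, lateral
    center-edge angle, posterior wall distance), reliability statistics
    (two-way random single-measure intraclass correlation with
    Landis-Koch interpretation), and group comparison / regression
    reports.  A parametric synthetic hip generator with analytic ground
    truth supports validation and simulation of multi-reader cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
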