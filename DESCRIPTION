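Package: osteoaxis
Title: Simulation of Mal-Angulated Femoral Rotational Osteotomies and the
    Mechanical Leg Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Parametric landmark-based models of the lower limb, virtual
    subtrochanteric and supracondylar rotational osteotomies with baseline and
    mal-angulated cutting planes, and measurement of the antero-posterior
    projected mechanical leg axis (hip-knee-ankle angle). Runs full factorial
    sensitivity grids over plane mal-angulation and fragment rotation and
    summarises the resulting frontal-plane alignment deviations with mean and
    standard deviation per condition, including a clinical relevance flag.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
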