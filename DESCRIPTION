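Package: atherosim
Title: Dynamic Modelling of Atherosclerotic Plaque Formation in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates atherosclerotic plaque formation in APOE-deficient mice
    with a seven-compartment ordinary differential equation model of blood and
    intimal lipids, monocytes, macrophages, foam cells and vessel radius.
    Diet and drug interventions (high-fat diet, antibiotics, IL-10 blockage,
    propionate) act through a piecewise-constant LDL-cholesterol uptake input.
    Provides weighted least-squares fitting of model parameters to sparse
    group-level time series by a (1+3)-evolutionary strategy with self-adaptive
    mutation step size, parametric-bootstrap confidence intervals, local
    sensitivity analysis, and a synthetic-data generator emulating the sparse
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    readr,
    yaml,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
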