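Package: aquaprog
Title: Probabilistic Screening Prognosis of Radionuclides in Aquatic Sediments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probabilistic prognosis of radionuclide activity concentrations
    in the bottom sediments of water bodies that receive routine liquid
    discharges from nuclear power plants.  Annual discharge series are turned
    into triangular release-rate distributions, propagated by Monte Carlo
    through generic steady-state screening dispersion models (reservoir box,
    river with partial lateral mixing, coastal lateral-Gaussian plume) and a
    sediment partitioning model with lognormal distribution coefficients and
    finite-time build-up.  Modelled distributions are compared against
    measured environmental concentration ranges, and a global-fallout
    baseline estimator attributes Cs-137/Sr-90 background.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
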