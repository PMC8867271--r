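Package: isruq
Title: Surrogate-Based Uncertainty Quantification for In-Stent Restenosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty quantification and variance-based sensitivity analysis
    of time-dependent in-stent restenosis simulations via surrogate modelling.
    Provides a proper-orthogonal-decomposition (POD) reduction of daily lumen
    quantities of interest coupled with per-coefficient Gaussian-process
    regression (ARD squared-exponential kernel), quasi-Monte Carlo forward
    uncertainty propagation with Sobol low-discrepancy sequences, and
    Saltelli/Jansen estimation of first-order and total Sobol sensitivity
    indices over time.  A phenomenological per-slice neointimal growth
    emulator generates training data with the qualitative dynamics of the
    cluster-scale three-dimensional restenosis model it stands in for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
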