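Package: ofmdiff
Title: Differentiable Enzyme-Constrained Flux Balance Analysis and
    Optimal Flux Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and solves enzyme-constrained flux balance analysis
    (ecFBA) problems, prunes optimal solutions to models with a unique
    optimum, and computes exact sensitivities of every solution variable
    (fluxes and enzyme concentrations) to every model parameter (turnover
    numbers, enzyme-pool capacities, fixed fluxes and bounds) by implicit
    differentiation of the Karush-Kuhn-Tucker conditions.  Optimal flux
    modes (OFMs) -- the analogue of elementary flux modes for models with
    inhomogeneous constraints such as ATP maintenance -- are enumerated by
    the Double Description method after slack-variable homogenization, the
    optimum is decomposed into OFM weights by nonnegative least squares,
    and the OFM weights are differentiated with respect to kinetic and
    capacity parameters.  Includes deterministic model generators, a native
    JSON model schema, best-effort COBRA-JSON import and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
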