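Package: relaxkin
Title: Temperature-Jump Relaxation Kinetics of Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of laser temperature-jump (T-jump) fluorescence
    relaxation experiments on ligand-binding enzymes, built around the
    single-tryptophan dihydrofolate reductase (DHFR) system. Simulates
    T-jump transients from a two-state binding model with an additional
    conformational relaxation, preprocesses raw transients (intrinsic
    tryptophan reference subtraction, normalization to percent change),
    fits double exponentials, classifies relaxation phases by their
    dependence on the sum of free enzyme and ligand concentrations, and
    extracts k_on, k_off and the kinetic dissociation constant. Also
    covers the equilibrium side: fluorescence band integration and
    percent-of-apoenzyme quenching tables, temperature-series correction,
    circular-dichroism thermal melt fitting, and relative activity from
    initial rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
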