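Package: sphingoem
Title: Ensemble Kinetic Modeling of the Plant Sphingolipid Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ensemble kinetic modeling of sphingolipid biosynthesis in
    Arabidopsis seedlings. Builds reference steady-state flux distributions from
    growth and composition measurements via parsimonious flux balance analysis,
    decomposes enzymatic reactions into elementary mass-action steps, samples
    thermodynamically consistent kinetic-parameter ensembles anchored to the
    reference state, screens models against experimentally observed responses to
    enzyme and regulator perturbations, ranks candidate ORM regulatory schemes,
    and compares apparent kinetic parameters (kcat+, Ks) between passing and
    failing models with two-sample Kolmogorov-Smirnov tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
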