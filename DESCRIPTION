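Package: neuromech
Title: Mechanochemical Analysis of Saltatory Neuronal Migration
Version: 0.1.0
Authors@R: person("neuromech", "maintainers", email = "maintainers@neuromech.dev",
    role = c("aut", "cre"))
Description: Quantitative toolkit linking leading-process extension to somal
    translocation in migrating neurons. Implements scanning ion conductance
    microscopy (SICM) stiffness mapping (approach-curve simulation, window
    slope fitting, Young's modulus inversion), bi-exponential FLIM lifetime
    fitting for membrane-tension probes, ratiometric calcium transient
    detection by the dF/F0 rule, single-cell migration track metrics
    (somal-translocation phase, migration and translocation speeds), rear-soma
    myosin activity quantification, a normality-gated statistical decision
    tree with small-sample permutation Spearman tests, and a seeded synthetic
    cohort generator implementing the integrated mechanochemical feedback
    model (extension -> tension -> mechanosensitive Ca2+ influx -> rear myosin
    -> somal step).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    optparse
Config/testthat/edition: 3
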