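Package: afmkvm
Title: Viscoelastic Kelvin-Voigt-Maxwell Analysis of AFM Force-Indentation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits an explicit Kelvin-Voigt-Maxwell (KVM) force-indentation
    relation to atomic force microscopy (AFM) approach curves acquired with
    spherical probes. Provides the full curve-analysis pipeline: tip-sample
    separation correction, baseline and contact-point estimation with a
    line-plus-polynomial model, bounded Nelder-Mead fitting of the KVM
    parameters (E0, E1, lambda, eta), geometric corrections for rounded
    cells (effective radius, confinement factor), and a finite-thickness
    (bottom-effect) error estimate. Includes a seeded synthetic-curve
    generator and an independent hereditary-integral forward model so
    every stage of the pipeline can be validated without instrument data,
    plus group-comparison statistics (Kruskal-Wallis with post-hoc t-tests)
    for batch studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
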