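Package: tensilefit
Title: Constitutive Modelling of Tensile Stress-Strain Curves for Nanofibrous Materials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for uniaxial tensile tests on soft fibrous
    materials such as electrospun nanofibrous mats, bundles and hierarchical
    muscle-like assemblies. Converts force-displacement records to apparent
    and porosity-corrected (net) stress-strain curves, extracts the classical
    mechanical indicators (offset yield, elastic modulus, asymptotic
    stiffness, failure point, strain-energy densities), and fits a composite
    constitutive model built from a linear-plus-saturating-exponential form
    (Z-Model) and the classical exponential soft-tissue toe-region form
    (F-Model), with inflection-point segmentation, continuity constraints at
    the joins, and an iterative backward search for the toe-to-linear
    transition point. Includes a synthetic-curve generator for the three
    archetypal curve shapes so that every stage of the pipeline can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
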