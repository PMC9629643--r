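Package: pclsoxy
Title: Steady-State Oxygen Transport in Cultured Precision-Cut Liver Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-analytical model of the steady-state oxygen partial-pressure
    field in a precision-cut liver slice (PCLS) suspended in culture media in
    one well of a multi-well plate. The axisymmetric diffusion-uptake problem
    is solved by eigenfunction expansion in an inner (tissue-bearing) cylinder
    and an outer fluid annulus, matched at the slice rim via Galerkin
    projection onto the inner vertical modes, with modified Bessel radial
    factors. Includes a conservative finite-volume reference solver for
    validation, scenario analyses over slice diameter, incubator oxygen level
    and slice placement, and search routines for placements that realise the
    physiological 35-65 mmHg internal oxygen gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
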