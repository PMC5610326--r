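Package: poredge
Title: Continuum Elastic Energetics of Pore Edges in Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the elastic energy and line tension of the edge of a
    transversal pore in a lipid bilayer within tilt-splay continuum elasticity.
    The membrane around the pore is decomposed into a quasi-flat bilayer region
    (solved with modified Bessel function bases) and a vertical edge-lining
    monolayer region (solved with exponential bases derived programmatically
    from the quadratic elastic functional), conjugated along a junction circle
    whose position is optimized by gradient descent. A water-filled hydrophobic
    defect is modelled as a cylindrical belt with a Marcelja-type interfacial
    energy, so that the full reversible trajectory from intact bilayer through
    hydrophobic defect to hydrophilic pore can be traced as a function of pore
    radius, yielding energy barriers, metastable pore states, and the
    radius-dependent line tension with its large-radius asymptote.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
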