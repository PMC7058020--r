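Package: raftline
Title: Elastic Energetics of Lipid Domain Boundaries and Membrane Inclusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-elastic model of the boundary between liquid-ordered
    and liquid-disordered lipid phases in a bilayer membrane, and of its
    deformation-mediated interaction with membrane inclusions.  The monolayer
    energy functional combines splay, tilt, lateral stretching and tension
    terms under a local volumetric incompressibility constraint; equilibrium
    deformation fields are found by direct constrained minimization of the
    discretized quadratic functional on a finite-difference grid.  Provides
    energy-versus-shift profiles of the bare domain boundary,
    energy-versus-position profiles for lipid stripes, amphipathic and
    hydrophobic peptides and transmembrane proteins, line-tension unit
    conversion, and Boltzmann enrichment estimates for lateral sorting
    predictions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
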