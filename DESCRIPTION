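Package: memscaffold
Title: Membrane-Mediated Interactions Between Rigid Curved Protein Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes the membrane-mediated interaction between two rigid,
    strongly anisotropic, intrinsically curved protein scaffolds (such as
    BAR-domain dimers) bound to a lipid membrane.  The membrane is represented
    as a triangulated surface whose Helfrich bending energy is minimized under
    normal-continuity boundary conditions along the scaffold perimeters.  From
    the minimized shapes the package assembles the orientation-optimized
    elastic interaction energy, the free energy of interaction obtained by
    Boltzmann integration over the scaffold orientation angles, and the
    resulting orientational-entropy repulsion, as functions of the
    inter-scaffold distance.  Includes a linearized Monge-gauge biharmonic
    solver used as an independent cross-check in the shallow-scaffold regime,
    far-field power-law fits, and scripted parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
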