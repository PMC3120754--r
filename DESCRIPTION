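Package: symmdef
Title: Modeling Arbitrarily Symmetric Macromolecular Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A general framework for modeling symmetric protein assemblies:
    symmetry definition files describing point, helical and crystal symmetry;
    virtual-frame kinematics with master/slave propagation of torsion and
    rigid-body degrees of freedom; weighted interface-multiplicity energy
    evaluation from an explicit subset of subunits; symmetric side-chain
    packing by simulated annealing; analytic gradient minimization of
    symmetric degrees of freedom (including cloned-jump derivative weights
    for lattice symmetry and correction gradients for asymmetrically applied
    whole-structure energies); and a symmetric rigid-body docking protocol.
    Energies are evaluated with a documented simplified pairwise potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
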