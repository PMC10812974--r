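Package: musclefem
Title: Finite-Element Simulation of Active Skeletal-Muscle Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A total-Lagrangian finite-element simulator for active skeletal
    muscle on tetrahedral meshes. Muscle is modelled as an incompressible,
    transversely isotropic hyperelastic composite with a Hill-type fiber
    stress (force-length, force-velocity, and neural-excitation-driven
    activation dynamics, with fast- and slow-twitch fiber mixing); bone and
    tendon are St. Venant-Kirchhoff elastic. Incompressibility is enforced by
    per-element Lagrange multipliers on linear tetrahedra, and fiber
    directions are obtained from the gradient of a Laplace potential. Includes
    a synthetic forearm geometry generator (radius, fusiform biceps, tendon
    straps), Gmsh MSH and VTK unstructured mesh input/output, uniaxial
    validation against a one-dimensional oracle, and parametric study runners
    for contraction velocity, fiber composition, maximum muscle stress, and
    neural excitation (sarcopenia scenarios), with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
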