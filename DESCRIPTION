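Package: brushpack
Title: Cell-Model Thermodynamics and 2D Monte Carlo for Crowded Spherical
    Polyelectrolyte Brushes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying crowding effects in quasi two-dimensional
    dispersions of spherical polyelectrolyte brushes such as DNA-coated
    colloids. Implements a Wigner-Seitz cell model of the brush free energy
    (Hartree electrostatics, chain elasticity, Flory excluded volume,
    counterion entropies and an osmotic insertion term) whose minimisation
    predicts counterion partitioning and packing-dependent particle
    shrinking; a 2D Metropolis Monte Carlo engine for disks with competing
    short-range attraction and Yukawa repulsion; structural analyses
    (radial distribution function, first-peak metrics, bond-orientational
    order parameter psi-6, neighbour statistics); drift-corrected
    mean-squared displacements with effective diffusion coefficients; and
    seed-deterministic generators for reference configurations and
    Brownian trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(load = "source")
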