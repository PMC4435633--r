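Package: cycluster
Title: Real-Space Cyclic-Cluster Semiempirical Molecular Orbital Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained NDDO semiempirical self-consistent-field engine
    (MNDO and AM1, sp basis) for molecules and for crystals treated with the
    real-space cyclic-cluster model of periodic boundary conditions. Two-electron
    integrals are Gaussian-damped towards their point-charge limit beyond a
    cutoff, distant electrostatic interactions are screened by a three-zone
    effective-distance scheme that contracts distributed multipoles to point
    charges, and exchange is restricted to the Wigner-Seitz cell, so that no
    reciprocal-space sampling is needed. Includes programmatic crystal and
    molecular fixtures (diamond, rocksalt, wurtzite, molecular boxes),
    extended-XYZ input/output, Coulson population analysis, carefully ordered
    compensated energy summation, and real-space local-property grids (electron
    density, electrostatic potential, local ionization energy and electron
    affinity) exportable as Gaussian cube files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
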