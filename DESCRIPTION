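Package: capsidstress
Title: Coarse-Grained Stress and Curvature Analysis of Icosahedral Viral Capsids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained mechanics of icosahedral viral capsids. Capsomers
    (pentamers and hexamers of coat proteins) are reduced to centroid point
    configurations, either generated as Caspar-Klug (h,k) lattices on
    icosahedra and spheres (including icosahedrally symmetric spherical codes
    that maximize convex-hull volume) or derived from experimental structure
    files. Neighbouring capsomers interact through a Lennard-Jones potential;
    the package computes the static virial stress tensor per capsomer, its
    tangential decomposition into lateral and maximum shear stress, and three
    discrete curvature measures (Gaussian angle defect, edge-dihedral mean
    curvature and capsomer-plane median curvature), and compares real capsid
    shapes against idealized icosahedral and spherical models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
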