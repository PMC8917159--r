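Package: rbcnet
Title: Red Blood Cell Deformability and Microvascular Network Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale computational study of how reduced red blood cell
    deformability alters microvascular hemodynamics. Provides a synthetic
    capillary-network generator, Skalak/Helfrich red-cell membrane mechanics on
    three-dimensional triangulated meshes and their two-dimensional contour
    analogs, an immersed-boundary unsteady Stokes flow core on a staggered grid
    with sharp-interface ghost-node walls, and the full analysis suite for
    paired normal-versus-stiffer-cell experiments: per-vessel hematocrit, flow
    and resistance statistics, bifurcation partitioning ratios and their
    disproportionality metrics, lingering detection at bifurcation apices, and
    wall shear stress maps with stiffness-induced change statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    yaml,
    igraph,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
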