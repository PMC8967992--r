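Package: npcorg
Title: Quantitative Analysis of Nuclear Pore Complex Organization from 3D-SIM-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitation pipeline for nuclear pore complex (NPC)
    organization in fission yeast nuclei imaged by three-dimensional structured
    illumination microscopy (3D-SIM). Provides a synthetic-nucleus generator
    (anisotropic Gaussian puncta on spheres with a Poisson/gain/read-noise camera
    model), iterative 3D spot detection by local-maximum tracking with spheroid
    masking, an outlier-tolerant convex-hull model of the nuclear envelope with
    surface area, volume and NPC density, two-channel co-detection, cell-cycle
    staging rules, single-particle averaging around the spindle pole body with
    exclusion-zone quantification, and nucleolar line-profile analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    minpack.lm,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
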