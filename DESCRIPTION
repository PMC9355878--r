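Package: lnmech
Title: Lymph Node Swelling Mechanics and Stromal Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for characterising the mechanics and
    stromal architecture of swelling lymph nodes. Inverts parallel-plate
    stress-relaxation measurements with a generalized Kelvin
    (double-exponential) model into effective resistance, Young's modulus
    and viscosity; derives capsule elasticity from micropipette aspiration
    via Laplace's law; measures stromal-network spacing by greedy packing
    of maximal inscribed circles and spheres into binary network masks;
    quantifies clonal clustering of sparse-labelled reticular cells with a
    sphere-contact DBSCAN and a Monte-Carlo spatial null (Cluster Factor);
    scores collagen-fibril alignment against a fitted conduit centerline;
    and extracts post-ablation recoil velocities from kymographs and
    pre/post-cut frame pairs. Seeded synthetic-data generators with known
    ground truth make every pipeline stage testable without raw imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
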