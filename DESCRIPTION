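Package: vasctree
Title: Morphometry, Similarity Testing, and Constructive Generation of
    Vascular Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and algorithmically generating vascular tree
    geometries such as hepatic portal and hepatic vein systems. Raw skeleton
    graphs extracted from medical images are repaired into strictly
    bifurcative geometric trees; edges are classified by Strahler and
    root-normalised Strahler* orders; per-edge geometric features (radii,
    lengths, decrease and asymmetry ratios, bifurcation exponents,
    bifurcation angles) are tabulated and compared between tree populations
    with two-sample Kolmogorov-Smirnov tests aggregated into a hierarchical
    weighted similarity score. Vascular trees are generated or extended by
    Constrained Constructive Optimization with a nonconvex-organ penalty,
    optional radius-dependent blood viscosity, and a calibrated
    bifurcation-angle postprocessing step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
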