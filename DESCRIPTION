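Package: dessolv
Title: Thermodynamic Taxonomy of API Solubility in Deep Eutectic Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a data-driven taxonomy of active pharmaceutical ingredient
    (API) solubility in deep eutectic solvents (DES) from COSMO-RS derived
    thermodynamic descriptors. Provides assembly and validation of the
    twenty-descriptor feature set (mixture-weighted solvent energies, relative
    solute-solvent descriptors, fusion thermodynamics), correlation-based
    principal component analysis with loading interpretation, deterministic
    k-means clustering with medoid/farthest-point (NANI) initialization, a
    cluster validation protocol combining silhouette scores with minimum
    inter-cluster Mahalanobis separation, mechanistic regime labeling with
    frozen-model projection of new systems, linear calibration reduction
    (LOD/LOQ), and a latent-factor synthetic data generator for end-to-end
    testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
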