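Package: zpocket
Title: Ligand Binding-Site Detection on Receptor Surfaces with 3D Zernike Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shape-complementarity analysis of protein-ligand recognition based
    on 3D Zernike moment invariants. Molecular surfaces are sampled as
    atom-attributed point clouds (parsed from DMS-style files or built
    internally), surface patches are cut around binding sites, size-matched
    decoy regions or residue-centered spheres, and each patch or ligand is
    voxelized into the unit ball and expanded in the orthonormal 3D Zernike
    basis. The rotation-invariant norms of the expansion coefficients give a
    36-number shape fingerprint (at order 10) whose Manhattan distance scores
    ligand-pocket compatibility; per-complex Z-score normalization, empirical
    association thresholds, ROC evaluation against decoys, and model-versus-
    experimental patch similarity analyses are included, together with a
    synthetic carved-pocket complex generator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
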