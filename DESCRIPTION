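Package: breastfem
Title: Patient-Specific Biomechanical Registration of Supine and Prone Breast Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable registration of breast images acquired in different
    postures (supine PET/CT versus prone MR) driven by a patient-specific
    biomechanical model. Provides a quasi-static total-Lagrangian finite-element
    solver for nearly incompressible neo-Hookean tissue under gravity on
    hexahedral meshes, estimation of the load-free reference configuration,
    inverse estimation of tissue stiffness by grid search on the nipple
    displacement, fuzzy c-means tissue segmentation, landmark-based rigid and
    similarity refinement, image warping through dense displacement fields, and
    target-registration-error evaluation. A seeded synthetic phantom generator
    supplies paired supine/prone test cases with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
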