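Package: scarconcord
Title: Concordance Between MRI-Derived Ventricular Scar and Electroanatomic Substrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement between late gadolinium enhancement
    (LGE) derived ventricular scar and catheter-based electroanatomic substrate
    maps. Provides full-width-half-maximum (FWHM) scar segmentation of LGE-like
    volumes, landmark rigid registration with iterative-closest-point refinement
    onto an endocardial surface mesh, Laplacian (relaxation) interpolation of
    sparse voltage and activation measurements over the mesh, nodal
    Sorensen-Dice concordance across bipolar voltage thresholds,
    stimulus-to-QRS conduction classification, and diagnostic-accuracy
    statistics (sensitivity, specificity, predictive values, ROC/AUC). A seeded
    synthetic left-ventricular phantom generator supplies ground-truthed test
    data in standard formats (NIfTI, PLY, CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'concordance.R'
    'diagnostics.R'
    'eam.R'
    'io.R'
    'mesh-io.R'
    'mesh.R'
    'phantom-config.R'
    'phantom.R'
    'pipeline.R'
    'plots.R'
    'registration.R'
    'segmentation.R'
    'tidiers.R'
    'utils.R'
    'volume.R'
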