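Package: fpetconn
Title: Subject-Level Metabolic Connectomics from Constant-Infusion PET and fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for subject-level metabolic connectomics:
    from dynamic constant-infusion [18F]FDG-PET and BOLD fMRI series (real or
    simulated) to modality-specific interregional connectivity matrices,
    significance-thresholded signed adjacency, multimodal common-edge
    connectomes with Soerensen-Dice similarity, nodal-degree group statistics
    with Bonferroni-Holm correction, and disease-severity correlations.
    Includes group spatial independent component analysis for intrinsic
    network identification, atlas-based region-of-interest extraction, and a
    fully synthetic multimodal cohort generator with known ground-truth
    network structure so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
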