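Package: hrfkit
Title: Whole-Brain Hemodynamic Response Function Estimation from Block-Design BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate and compare species-specific hemodynamic response
    functions (HRFs) from task fMRI block designs. Implements the two-gamma HRF
    model with species presets, construction of canonical (1st/3rd order) and
    finite-impulse-response (FIR) design matrices, voxelwise GLM detection with
    uncorrected-p plus cluster-extent thresholding, activation-probability maps
    and Dice similarity, structure-wise BOLD epoch extraction with amplitude and
    decay quality criteria, bounded multi-start nonlinear least-squares HRF
    fitting with normalized-MSE and onset quality control, whole-brain HRF
    aggregation, and a functional two-sample max-t permutation test with
    Bonferroni family control. A synthetic-data module generates labeled 4D
    BOLD datasets with known ground truth emulating a rodent somatosensory
    block-design acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
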