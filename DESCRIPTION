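Package: imgtx
Title: Imaging Transcriptomics of Local Spontaneous Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for transcriptome-neuroimaging association
    analysis of resting-state fMRI. Computes voxel-wise local activity metrics
    (regional homogeneity via Kendall's coefficient of concordance, ALFF and
    fALFF) from 4D BOLD volumes after nuisance regression and bandpass
    filtering; derives case-control t-maps with permutation-based cluster-level
    family-wise-error inference; processes donor-brain microarray bundles into
    a normalized sample-by-gene expression matrix (intensity filtering,
    RNA-seq-guided probe selection, scaled robust sigmoid normalization,
    differential-stability gene selection); and correlates gene expression with
    t-values sampled in spheres at tissue-sample coordinates, with Bonferroni
    correction and risk-gene intersection. A synthetic-data module generates
    every input with planted effects so the whole pipeline is exercisable and
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
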