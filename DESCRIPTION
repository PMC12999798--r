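Package: fdgensemble
Title: Hierarchical Ensemble Classification of Dementia Subtypes from FDG-PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for four-class differential diagnosis of dementia
    (Alzheimer's disease, dementia with Lewy bodies, mixed AD/DLB
    pathology, and healthy controls) from FDG-PET brain volumes.
    Implements standardized-uptake-value-ratio (SUVR) normalization to a
    cerebellar gray-matter reference, subject-residual-profile (SRP)
    images via log-transform and double centering on a study-specific
    gray-matter mask, small 3D convolutional binary classifiers with a
    multi-scale context module, a multiclass head built from their
    frozen feature extractors, a three-step hierarchical ensemble
    decision rule, and Grad-CAM saliency aggregation with atlas-based
    region-of-interest reporting.  A synthetic brain-phantom cohort
    generator with class-specific regional metabolic signatures makes
    the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
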