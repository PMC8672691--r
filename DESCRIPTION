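Package: voxenc
Title: Voxelwise Encoding Models for Natural-Language fMRI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and evaluates voxelwise encoding models of BOLD responses to
    natural speech. Stimulus events (words, phonemes, audio frames) are turned
    into hierarchical feature spaces (mel spectrogram, articulatory features,
    part of speech, word-level and context-level semantic embeddings),
    Lanczos-resampled to the scanner TR, z-scored and expanded with finite
    impulse response delays, and regressed against voxel time series with
    ridge regression under a single bootstrap-selected regularization value.
    Model performance is scored as signed squared correlation on held-out
    stories, corrected for repeat reliability with a floored normalized
    correlation coefficient, and decomposed into unique and pairwise variance
    partitions with a constrained minimum-norm bias correction. Inference uses
    block permutation tests with Benjamini-Hochberg FDR control, and semantic
    model weights are summarized with PCA plus spherical k-means clustering.
    A synthetic-data module generates stimulus streams and BOLD responses with
    known ground-truth variance structure so every stage can be validated
    against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    data.table,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'features.R'
    'audio.R'
    'inference.R'
    'clustering.R'
    'encoding.R'
    'feature-tables.R'
    'io.R'
    'noise-ceiling.R'
    'varpart.R'
    'preprocess.R'
    'synthetic.R'
    'pipeline.R'
    'voxenc-package.R'
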