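Package: voxlica
Title: Voxel-Linked Independent Component Analysis of Multimodal Brain Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variational-Bayes Linked Independent Component Analysis for two or
    more feature-by-voxel data matrices that share a common voxel grid, such as
    volumetric gene-expression energy and axonal projection density registered
    to a common anatomical template. The model factorises every modality into
    shared sparse spatial sources, modality-specific feature coefficients and
    non-negative modality weights, with automatic relevance determination over
    components and per-modality Gaussian noise models. Includes volumetric
    preprocessing (masked trilinear downsampling, voxel masking, row-major
    flattening, region-mean imputation), dictionary learning and sparse coding
    comparison factorisations, percentile thresholding and modality-dominance
    analysis of spatial maps, hypergeometric gene-set over-representation
    analysis with FDR control, reconstruction scoring, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    glmnet,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
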