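Package: TCPermute
Title: Total-Variation Constrained Permutation for Single-Cell Copy-Number Seriation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of a sample ordering and a denoised signal matrix
    from noisy single-cell DNA-sequencing read-depth profiles. A row permutation
    P and a recovered matrix X are fitted to the observed matrix B by minimizing
    the energy ||PX - B||^2_F + alpha * ||X||_{TV,l1} with an alternating
    augmented-Lagrangian (ADMM-style) scheme: an FFT-diagonalized least-squares
    X-step, a soft-thresholding Y-step, and a Kuhn-Munkres linear-assignment
    P-step. Stacking similar cells into contiguous blocks reveals shared
    copy-number patterns. Includes a block-structured synthetic data generator
    with SNR control, a Laplacian-Score feature pre-filter for irrelevant
    read-depth signals, sorting and hierarchical-clustering baseline orderings,
    and evaluation metrics for block recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SingleCell, Sequencing, Clustering
RoxygenNote: 7.3.3
Collate: 
    'TCPermute-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'difference-operator.R'
    'norms.R'
    'updates.R'
    'refine.R'
    'solver.R'
    'synthetic.R'
    'laplacian-score.R'
    'baselines.R'
    'io.R'
    'cli.R'
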