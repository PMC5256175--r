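Package: tractoval
Title: Tractogram Quality Assessment and Fiber Up-Sampling for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Microstructure-informed evaluation and repair of diffusion MRI
    tractograms. Fits per-streamline and per-compartment contributions to the
    measured diffusion signal with a Stick-Zeppelin-Ball dictionary solved by
    non-negative FISTA, quantifies the residual directionally (error fiber
    orientation distributions via constrained spherical deconvolution, error
    fractional anisotropy via a tensor fit, NRMSE) along segmented fiber
    bundles with Mahalanobis-weighted 100-node tract profiles, and up-samples
    under-represented bundles by Gaussian sampling in a PCA space of
    equidistant point descriptors with distance- and mask-based rejection.
    Includes a synthetic phantom generator (crossing and curved bundles with
    known ground truth) and nonparametric max-statistic permutation testing
    of tract profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
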