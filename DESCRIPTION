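Package: bsir
Title: Scalable Bayesian Image-on-Scalar Regression with Low-Rank
    Gaussian Process Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully Bayesian group-level image-on-scalar regression for
    neuroimaging data.  Spatially varying covariate effects and
    participant-specific deviations receive Gaussian-process priors with a
    Matern covariance kernel; a Nystrom low-rank approximation with a
    Karhunen-Loeve reparameterization reduces inference to a small number
    of basis coefficients, fitted either by a conjugate Gibbs sampler or
    by mean-field coordinate-ascent variational inference.  Includes
    massive-univariate GLM and voxelwise Bayesian multilevel baselines,
    evidence (Es) maps and activation thresholding, posterior predictive
    checks, leave-one-out selection of the basis size, a synthetic-data
    generator for two-region sparse activation designs, NIfTI input and
    output, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
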