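Package: kernelconn
Title: Voxel-Scale Connectome Inference by Division-Restricted Kernel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers a nonnegative voxel-to-voxel brain connectivity matrix
    from anterograde viral tracing experiments using a Nadaraya-Watson
    kernel estimator with a Gaussian spatial kernel restricted to major
    brain divisions. Provides closed-form leave-one-out cross-validation
    for bandwidth selection, regionalization operators that aggregate the
    factored voxel connectome to a parcellation, a regionally homogeneous
    baseline model fit by nonnegative least squares, statistical analyses
    of connection-weight distributions and their distance dependence, and
    a synthetic-data generator that simulates tracing experiments from a
    smooth ground-truth connectome for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    pracma,
    mclust,
    fitdistrplus,
    minpack.lm,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
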