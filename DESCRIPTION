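Package: l2ocert
Title: Implicit Learning-to-Optimize Models with Trustworthiness Certificates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building implicit learning-to-optimize (L2O) models whose
    inference is the fixed point of a tunable optimization iteration, together
    with a certificate system that labels every inference pass/warning/fail by
    ranking interpretable property values (sparsity, measurement fidelity,
    constraint distance, total variation, iterate and proximal residuals)
    against an empirically calibrated distribution. Includes a linearized-ADMM
    solver for composite constrained problems, a parallel-beam Radon operator
    for sparse-angle computed-tomography reconstruction, an implicit dictionary
    model for sparse signal recovery, Jacobian-free training, and synthetic
    data generators for both experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    graphics,
    stats,
    utils
Suggests:
    pracma,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
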