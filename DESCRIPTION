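Package: diltest
Title: Entropy-Based Two-Sample Tests for the Dilation Order
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric evidence functions and two-sample tests for the
    dilation (variability) order built from cumulative residual entropy (CRE)
    and cumulative entropy (CE). Provides L-statistic estimators of CRE and CE
    with spacings-based variance estimators, asymptotic and Monte-Carlo
    decision rules, one-sample tests of exponentiality against HNBUE/HNWUE
    aging alternatives, four competitor dispersion statistics, absolute
    Lorenz-curve diagnostics for verifying the dilation order between
    parametric models, and a simulation engine for size/power studies and
    normality diagnostics of the null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
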