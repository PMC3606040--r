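Package: bulksolv
Title: Fast Bulk-Solvent and Overall Anisotropic Scaling of
    Crystallographic Structure Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic determination of mask-based bulk-solvent scale
    factors and overall (isotropic and anisotropic) scaling for
    macromolecular crystallographic structure factors.  Per resolution
    bin, the overall and bulk-solvent scales are obtained as roots of a
    cubic equation derived from the least-squares normal equations, so
    no iterative local optimization is required.  The overall
    anisotropic scale factor is fitted either as an exponential model
    with crystal-system symmetry constraints (analytic log-linear
    solve, optionally polished by quasi-Newton minimization) or as an
    unconstrained polynomial model (12-parameter linear solve).
    Includes logarithmic ln(d) resolution binning with a per-bin count
    floor, Savitzky-Golay smoothing of bin-wise scale curves,
    twin-fraction estimation by a constrained (Lagrange) linear system
    interleaved with scaling, a synthetic-data generator with known
    ground truth, reflection-file readers and writers (columnar text
    and mmCIF refln records), and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
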