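Package: mp2ratio
Title: Simulation and Comparison of MP2RAGE R1 and T1w/T2w Ratio Cortical Mapping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate quantitative MRI acquisitions of a digital
    two-hemisphere brain phantom and to compare two cortical "myelin" mapping
    strategies: B1-corrected R1 mapping from the MP2RAGE sequence and
    T1w/T2w ratio mapping with receive-bias and residual-bias correction.
    Includes closed-form steady-state signal models for MP2RAGE, MPRAGE and
    SPACE sequences, lookup-table T1 inversion, bias-field preprocessing
    chains, surface-based cortical map construction (volume-to-surface
    sampling, geodesic smoothing, gradients, parcel statistics), and a
    test-retest / effect-size / hemispheric-symmetry statistical battery,
    together with minimal NIfTI-1 and GIFTI readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
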