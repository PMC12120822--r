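Package: etherims
Title: Ion Mobility Statistics for Ether Lipid Annotation
Version: 0.1.0
Authors@R: person("etherims", "developers", role = c("aut", "cre"),
    email = "etherims@example.org")
Description: Tools for assessing how well trapped ion mobility collision
    cross sections (CCS) discriminate 1-O-alkyl from 1-O-alkenyl
    (plasmalogen) phosphatidylethanolamines in 4D lipidomics experiments.
    Provides a lipid shorthand parser with monoisotopic [M-H]- mass
    computation, a synthetic cohort generator emulating a wild-type vs
    Peds1-deficient mouse tissue design, per-sample linear CCS calibration
    against 1-acyl reference values and linear retention-time alignment,
    matched structural pair-delta statistics, five-coefficient linear
    RT/CCS trend models with measured-vs-predicted database comparison,
    and a Gaussian two-peak overlap model converting ion mobility
    resolving power into annotation error probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
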