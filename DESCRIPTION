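Package: mp2rageme
Type: Package
Title: Bloch Simulation and Quantitative T1/T2* Mapping for the MP2RAGEME Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal modelling and quantification tools for the MP2RAGEME
    sequence, an inversion-recovery gradient-echo acquisition in which the
    second readout block is extended to multiple echoes so that T1, T2* and
    susceptibility-weighted data are acquired in a single scan. Provides the
    periodic steady-state Bloch signal model for MP2RAGE-family protocols,
    lookup-table T1 estimation with transmit-field (B1+) correction,
    mono-exponential multi-echo T2* fitting, Bland-Altman agreement
    statistics, simulations of B1+ sensitivity and of T1-induced
    point-spread-function blurring in segmented k-space acquisitions, a
    synthetic 3-D multi-tissue phantom generator with Rician noise, and
    NIfTI-1 input/output for the full quantification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
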