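Package: trpfluor
Title: Time-Resolved Tryptophan Fluorescence Analysis for Membrane-Active Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for time-correlated single-photon counting
    (TCSPC) studies of tryptophan-labelled membrane-active peptides:
    iterative-reconvolution multi-exponential decay fitting, time-resolved
    emission spectra (spectral center of gravity, FWHM, dipolar-relaxation
    fits), global time-resolved anisotropy analysis, global Stern-Volmer
    collisional-quenching analysis, calcein-leakage quantification,
    membrane-partition titration fitting with support-plane (NSSR)
    confidence intervals, and partition-weighted decomposition of
    observables into aqueous and membrane-bound endpoints.  Includes a
    seeded synthetic-data generator emulating the underlying TCSPC
    experiments so the full pipeline can be exercised end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
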