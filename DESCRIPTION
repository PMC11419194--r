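Package: hp13c
Title: Hyperpolarized 13C-Pyruvate Renal Metabolic MRI Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for dynamic hyperpolarized [1-13C]pyruvate
    MRI of the kidney: a digital-kidney phantom generator (two-site exchange
    kinetics, multi-channel coil model, correlated complex noise), multi-coil
    reconstruction (noise pre-whitening, AUC-based sensitivity estimation,
    matched-filter combination, Fermi-filtered zero-fill), real-time prescan
    emulation (bolus detection, centre-frequency calibration), normalized
    metabolite-to-pyruvate AUC ratio analysis with mean-time timing correction
    and ROI/group statistics, and companion proton ADC and R2* relaxometry
    fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
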