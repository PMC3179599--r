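Package: ktperf
Title: First-Pass Myocardial Perfusion MRI Simulation, k-t PCA
    Reconstruction and Quantification for Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-pass contrast-enhanced myocardial perfusion
    MRI in small animals at very high heart rates. Provides a seeded
    digital mouse-heart phantom with known myocardial blood flow (MBF),
    a sheared-lattice k-t undersampling simulator with central training
    profiles, a k-t principal-component-analysis constrained
    reconstruction, three-sector myocardial signal-intensity curve
    extraction, and semiquantitative (enhancement ratio, five-point
    maximal upslope, normalized upslope) plus absolute (Fermi-constrained
    deconvolution) perfusion quantification. Images are exchanged as
    NIfTI-1, curves and metrics as CSV, and configurations and
    provenance as YAML/JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    mgcv,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
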