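Package: texrep
Title: Repeatability and Robustness of MRI Texture Features on Simulated Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates magnetic-resonance phantom acquisitions (uniform water and
    textured tissue objects, magnitude-image noise, test-retest repositioning),
    extracts 46 radiomic features (14 first-order statistics plus 32 grey-level
    co-occurrence and run-length texture features) from fixed circular regions of
    interest, perturbs image noise (NEX-scaled Gaussian) and spatial resolution
    (bicubic downsampling with antialiasing), and quantifies feature robustness
    and repeatability via the percentage coefficient of variation, Pearson
    correlation with the acquisition parameter, and Lin's concordance
    correlation coefficient, with the standard classification bins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
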