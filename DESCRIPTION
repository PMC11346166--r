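Package: robunet
Title: Robust U-Net Architecture Search for Cross-Modality Medical Image Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches a configurable U-Net encoder-decoder space for
    architectures that translate MR image slices into CT images (in
    Hounsfield units) while remaining robust to adversarial (fast gradient
    sign method) and Gaussian input corruption.  Provides the categorical
    architecture space with exact combinatorics, a self-contained
    convolutional network engine with reverse-mode gradients for both
    weights and inputs, FGSM and Gaussian corruption generators,
    regular and adversarial (Bernoulli loss-mixing) training, HU-region
    Dice and mean-absolute-error evaluation, random and Tree-structured
    Parzen Estimator search strategies, a paired head-phantom generator
    standing in for institutional MR/CT data, and an end-to-end
    experiment pipeline with seed- and data-sensitivity protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
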