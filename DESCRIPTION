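Package: seldiproc
Title: SELDI-TOF Spectrum Preprocessing with Wavelet Denoising and
    Neural-Network Peak Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and peak-validation toolkit for SELDI-TOF mass
    spectrometry. Implements a quadratic-variance-function (QVF) detector
    noise model estimated from peak-free regions, variance-stabilized
    translation-invariant wavelet denoising via cycle spinning with a cached
    sparse orthonormal wavelet operator, a zero-phase equiripple FIR
    low-pass smoother (Parks-McClellan design) for peak quantification,
    cross-spectrum peak clustering with a mass-tolerance prevalence rule, a
    62-feature feed-forward neural-network peak validator trained by
    Polak-Ribiere conjugate gradients on a regularized cross-entropy
    objective, and case/control group statistics including the mid-P Fisher
    exact test on cluster prevalences. A synthetic-spectrum generator with
    full ground truth supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
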