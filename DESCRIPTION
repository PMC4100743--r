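Package: maskedlbp
Title: Occlusion-Aware Patch-Based Face Verification with Masked LBP Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Verifies disguised or occluded face images by first deciding,
    patch by patch, whether a face-grid cell shows genuine facial appearance
    (biometric) or an accessory such as sunglasses, a scarf or a wig
    (non-biometric), and then matching only the patches that both images of a
    pair agree are biometric. Patches are described by a 512-dimensional
    concatenation of a 256-bin intensity histogram and a 256-bin local binary
    pattern (LBP) histogram, classified with an RBF-kernel support vector
    machine, and compared with a chi-squared histogram distance averaged over
    the usable patches. Includes the verification evaluation protocol (ROC,
    GAR at fixed FAR, EER, disguised-region error analysis) and a seeded
    synthetic disguised-face generator with ground-truth patch annotations so
    the full pipeline can be exercised without access to restricted face
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
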