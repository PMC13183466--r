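Package: larvatrack
Title: Quantification of Optogenetically Evoked Larval Contraction and Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for an optogenetic Drosophila larval
    motor-performance assay. Segments a crawling larva in grayscale video
    (Gaussian blur, rolling-ball background subtraction, Otsu thresholding),
    tracks the animal's outline perimeter frame by frame, decodes the optical
    stimulus state from an in-frame indicator LED, and computes cycle-resolved
    contraction amplitudes and fatigue statistics. Also includes a two-channel
    ROI-based quantification of presynaptic mitochondrial content and a
    synthetic phantom generator with analytic ground truth, so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
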