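Package: endoct
Title: Endoscopic OCT Analysis of Murine Colitis: Segmentation, Thickness
    and Attenuation Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for helical-scan endoscopic optical coherence
    tomography (OCT) of the mouse colon. Frames raw A-scan streams into
    B-scans, segments and flattens the colon wall (Canny edge detection,
    hole filling, morphological closing, binary masking), reconstructs
    circular cross-sections and enface views, and quantifies wall thickness
    and Beer-Lambert attenuation coefficients per layer. Includes a
    synthetic phantom generator for a four-layer cylindrical colon wall
    (Beer-Lambert decay, multiplicative speckle, sheath-detachment gaps,
    motion jitter, colitis effects) with full ground truth, and study-level
    two-way group-by-day ANOVA for longitudinal colitis monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
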