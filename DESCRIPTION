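Package: ovograde
Title: Non-Destructive Egg Grading and Freshness Assessment from Images and Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades chicken eggs and scores their freshness without water
    displacement or flotation. A machine-vision pipeline measures egg length
    and breadth from a calibrated top-down photograph (median denoising,
    grayscale conversion, Otsu segmentation, principal-axis extents); together
    with the weight this yields the ellipsoid volume V = pi*L*B^2/6, the
    density rho = m/V, a weight-based size class (jumbo through small), a
    freshness percentage relative to the size class's fresh-laid density, and
    a high/medium/low freshness band from density thresholds. Includes seeded
    synthetic generators (egg images with exact geometric ground truth,
    storage-time weight-decay series), ordinary least squares storage-decay
    models, chemometric agreement statistics (RMSEC, RPD), batch processing
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
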