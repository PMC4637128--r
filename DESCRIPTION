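Package: clift
Title: Automated Classification of Crithidia luciliae Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated evaluation of Crithidia luciliae based
    indirect immunofluorescence tests (CLIFT) for anti-dsDNA antibodies.
    Implements the full image-classification chain: registration of paired
    green (FITC) and red (Evans blue counterstain) fluorescence channels,
    focus and artefact quality control, adaptive-threshold cell segmentation,
    per-cell shape quality control, axis-profile feature extraction, linear
    discriminant cell classification by kinetoplast fluorescence, image- and
    sample-level verdicts with titer estimation, and evaluation statistics
    against expert visual reads. Ships a dual-channel synthetic image
    simulator with per-cell ground truth so every stage is testable without
    access to incubated slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
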