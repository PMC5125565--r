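Package: mcquant
Title: Quantification of Mast Cells in IHC-Stained Skin Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided tissue analysis for quantifying tryptase-positive
    mast cells in brightfield immunohistochemistry images of skin. Separates
    hematoxylin and AEC stains by color deconvolution, segments nuclei on the
    hematoxylin channel, delineates dense lymphoma infiltrates from a
    Parzen-window cell-density map, constructs 30/60 micrometre proximity
    bands by distance transformation, detects mast cells on the tryptase
    channel with a compact-versus-fragmented degranulation classifier, and
    summarises per-region densities with exact nonparametric cohort tests.
    Ships a synthetic-image generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
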