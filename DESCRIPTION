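Package: timetopo
Title: Spatial Tumor-Immune Microenvironment Topography for Multiplex IHC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phenotyped single-cell tables exported
    from multiplex immunohistochemistry of head and neck cancer specimens.
    Constructs tumor tissue zones (tumor area, invasive margin, tumor
    center, tumor field versus stroma) from tumor-field polygon
    annotations, computes zone-wise immune cell densities and classifies
    specimens into four CD8-based immunotypes (fully infiltrated,
    stroma-restricted, immune-excluded, immune-desert), measures average
    minimum distances and within-radius contact fractions between
    phenotype pairs, clusters immune cells into cellular neighborhoods
    from 50 micrometer neighbor-count profiles, processes Olink NPX
    secretome matrices (presence filtering, plate intensity
    normalization, hierarchical clustering, density correlations), and
    provides the accompanying nonparametric testing layer. Includes a
    synthetic tissue generator emulating the four immunotype archetypes
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
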