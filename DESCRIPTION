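Package: seedstage
Title: Image-Based Maturity Staging and Sensory-Instrumental Texture
    Analysis of Grape Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for staging grape seeds by ripeness from cabinet
    photographs and for relating the stages to instrumental texture and
    sensory panel data. Provides sRGB to CIELAB colorimetry under D65/2
    degrees, grid-wise seed segmentation and per-seed colour summaries,
    percentile allocation of seeds into equal-size maturity stages from
    lightness and chroma, extraction of ten compression-test texture
    parameters from force-distance curves (peaks, breaking force and
    decline, elasticity, energies, thickness, strain index, area ratio),
    sensory panel performance statistics (balanced three-way ANOVA,
    Student-Newman-Keuls letters, judges-as-variables homogeneity PCA,
    judge screening), and sensory-instrumental integration (stage
    summaries, correlation matrices, redundancy pruning, Kaiser-criterion
    PCA). A synthetic-data module generates seed images, force-distance
    curves and panel score tables with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    png,
    pracma,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
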