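Package: epistrat
Title: Division Orientation, Cell Geometry and Planar Polarity in Stratifying Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of three-dimensional basal-cell division
    orientation and daughter positional fate from tracked nuclear centroids,
    interphase cell-shape morphometrics (cross-sectional area, apical-basal
    height, longest planar axis, elongation nematic, polygon class, density,
    proliferation, tissue thickness), junctional planar-cell-polarity
    nematics, and a two-sample Kuiper test adapted to division angles
    restricted to the 0-90 degree range.  Includes a seeded synthetic
    basal-layer generator (Lloyd-relaxed bounded Voronoi packing, nuclear
    tracks, division events with angle-coupled fates, and polarized edge
    intensities) so that every analysis stage is verifiable by parameter
    recovery without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
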