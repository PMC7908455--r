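Package: swotahp
Title: Quantitative SWOT Analysis with AHP Weighting and Strategic Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative SWOT (strengths, weaknesses, opportunities,
    threats) strategic analysis using the analytic hierarchy process (AHP).
    Builds and validates positive reciprocal pairwise-comparison matrices on the
    Saaty scale, derives priority weights by the product-square-root (geometric
    mean) method with lambda-max/CI/CR consistency diagnostics, converts 0-5
    estimated strengths into signed factor and group intensities, and summarises
    the four group totals as a strategic quadrilateral with centroid, azimuth
    angle, positive/negative strategic intensities and intensity coefficient,
    classifying the result into the SO/WO/WT/ST strategy spectrum. Includes a
    synthetic expert-panel generator (log-normal judgment noise, optional Saaty
    quantization) for simulation studies, YAML/JSON configuration input,
    JSON/Markdown reporting, and plotting of the quadrilateral and the polar
    strategy spectrum. Ships a worked case study on the development of
    home-based exercise in China as a bundled fixture.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
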