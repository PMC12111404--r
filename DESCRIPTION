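Package: dephenolize
Title: Surrogate-Based Optimization of Rapeseed-Cake Dephenolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing ethanol-wash dephenolization of rapeseed
    press cake before protein isolation. Fits a three-layer hyperbolic-tangent
    multilayer perceptron to total-phenolic-yield experiment tables by
    Levenberg-Marquardt least squares, attributes input importance from the
    trained connection weights (Yoon's method), and searches the process box
    (ethanol concentration, solid-to-liquid ratio, sonication time) with a
    particle swarm optimizer checked against a dense grid oracle. A synthetic
    response-surface generator with a known optimum and known main-effect
    ordering makes every stage verifiable end to end. Also implements the
    standard protein-chemistry bookkeeping around the process: extraction
    yield from protein mass balances, Bradford soluble-protein concentration,
    Folin-Ciocalteu gallic-acid-equivalent quantitation, amino-acid profile
    summaries against WHO essential-amino-acid thresholds, and the
    TCA-soluble digestibility gain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
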