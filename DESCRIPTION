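Package: forestchange
Title: Change Indicators, Spatial Patterns and Driver Attribution for
    Permanent-Plot Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify structural and compositional change in
    repeatedly censused permanent-plot forest inventories. Computes nine
    plot-level indicators (basal area, stand density, large-tree density,
    dbh variation, conifer and seral-class shares, Hill-number diversity),
    annualized and standardized change rates, acceleration of change
    between census periods, variogram-based ordinary kriging of change
    surfaces, and attribution of change to legacy, disturbance, climate
    and site drivers with cross-validated boosted regression trees and
    backward covariate elimination. A synthetic mountain-landscape
    generator with recorded ground truth makes the full pipeline testable
    without access to a real inventory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
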