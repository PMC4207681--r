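Package: fallowsim
Title: Uncertainty and Sensitivity Analysis of Farmland-Conservation
    Agent-Based Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates voluntary enrollment of farmland in a conservation
    set-aside program (modelled on the U.S. Conservation Reserve Program) on a
    raster landscape: farmer agents decide their willingness to enroll with
    ordered-weighted-averaging (OWA) decision rules and neighbourhood
    imitation, build discounted payment offers over ranked parcel sites, and a
    program agency ranks and accepts a capped number of offers each year for
    ten years.  The simulator is wrapped in a variance-based uncertainty and
    sensitivity engine: Sobol' quasi-random sampling, Saltelli block designs,
    first-order and total-effect index estimation with bootstrap errors, and
    the two model-simplification procedures they support (fixing negligible
    factors for an exploratory model, fixing the dominant factor for an
    explanatory model).  A seeded synthetic-landscape generator makes the
    whole pipeline runnable without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
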