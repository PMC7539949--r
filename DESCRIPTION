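Package: porespace
Title: Dynamic Soil Pore-Space Accounting, Water Retention and
    Bioturbation-Driven Structure Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Volume and porosity bookkeeping for a three-class
    (micro/meso/macro) textural-structural soil pore model, coupled to a
    dynamic van Genuchten water retention curve with a texture-fixed shape
    parameter n and a pore-pool-derived alpha.  Pore-change factors map
    solid-volume fluxes from root growth and decay, earthworm ingestion and
    casting, microbial organic-matter turnover and swelling or shrinkage onto
    the structural pore classes.  Includes closed-form steady states and
    ODE simulations of soil structure recovery after compaction, a
    surface-casting model with a macroporosity-threshold casting function,
    and multi-start calibration of the bioturbation parameters with Powell's
    derivative-free conjugate-direction method.  Synthetic retention-curve
    and recovery-series generators with known ground truth support
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
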