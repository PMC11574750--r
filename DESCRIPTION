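Package: vacomhta
Title: Early Health-Economic Evaluation of a Soft Robotic Sock for Post-Stroke Venous and Contracture Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-period decision-tree cost-utility model comparing a soft
    robotic sock (VACOM, combining intermittent pneumatic compression with
    robotic ankle mobilisation) against intermittent pneumatic compression
    plus manual ankle movement in post-stroke inpatients, over a one-year
    horizon from a healthcare-system perspective. Provides exact pathway
    enumeration and a microsimulation cross-check, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, one-way
    deterministic sensitivity analysis with net-monetary-benefit tornado
    ranking, price-premium threshold analysis for target product profiling,
    and value-of-information analysis (EVPI and per-parameter EVPPI by
    nested Monte Carlo and regression estimators). A synthetic parameter-table
    generator reproduces the structure of the literature-derived parameter
    set so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
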