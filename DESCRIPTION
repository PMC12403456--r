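Package: fpmarket
Title: Agent-Based Simulation of a Segmented Family-Planning Market
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-vendor family-planning market in which one free
    public venue and one priced private venue compete for a heterogeneous
    population of women who differ in income, sensitivity to service quality,
    and location. A policymaker allocates a fixed monthly budget among
    truthful quality advertising, true quality improvement, and private-sector
    price support; the package runs burn-in/policy-switch experiments in urban
    and rural market geometries, perturbs structural parameters for
    sensitivity analysis, and estimates the policy effect on the modern
    contraceptive prevalence rate (mCPR) with a pre/post dummy-variable
    regression on iteration-month panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
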