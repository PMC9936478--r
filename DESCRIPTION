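Package: amews
Title: Agent-Based Early Warning Simulation of Household Food Security
    and Acute Malnutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An evidence-driven agent-based model of household
    food-security behaviour for acute-malnutrition early warning.
    Households hold portfolios of livelihood strategies (own food
    production, local networks, buy/barter), select among them by past
    performance, and adapt by a hill-climbing heuristic that imitates the
    best-performing geographic neighbours. Climate (NDVI anomaly) and
    market (staple price) stressors act as multiplicative effectiveness
    factors on strategy dimensions. The package aggregates simulated
    household outcomes to ward-month acute-malnutrition prevalence,
    classifies prevalence on the five-phase IPC acute-malnutrition scale,
    and provides calibration by grid search, temporal-split and rolling
    leading-edge forecast validation (macro F1, Hamming loss, RMSD, joint
    validity), counterfactual shock scenarios, and a generator of
    synthetic sentinel-site surveillance data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
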