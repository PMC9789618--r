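Package: cidemand
Title: System Dynamics Simulation of Cochlear Implant Demand and Payer Cost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time (daily step) stock-and-flow simulation of cochlear
    implant (CI) demand and statutory-health-insurance cost in an aging
    population. Maintains an age-by-disease-stage population (healthy,
    CI-relevant hearing loss, unilateral CI, bilateral CI) under fertility,
    mortality and cohort aging; derives age-specific hearing-loss incidence
    from grouped prevalence via an exponential least-squares fit; computes
    implantation, speech-processor exchange and reimplantation flows from
    age-specific feasibility and willingness schedules; and converts flows
    into annual payer cost components. Includes named scenario presets with
    linear parameter ramps, one-way tornado sensitivity analysis, calibration
    of willingness to observed implantation counts, and a self-contained
    stylized-country input generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
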