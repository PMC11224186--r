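Package: recruitquant
Title: Quantitative CT and Bedside Assessment of PEEP-Induced Lung Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify positive end-expiratory pressure (PEEP) induced
    alveolar recruitment and lung strain in the acute respiratory distress
    syndrome. Implements quantitative CT densitometry (Hounsfield-unit
    gas/tissue decomposition, aeration compartments, tissue and gas
    recruitment), processing of ventilator flow and airway-pressure waveforms
    into respiratory mechanics (plateau pressure, driving pressure,
    compliance, stress index, ventilatory ratio, airway opening pressure),
    the one-breath derecruitment maneuver yielding the
    recruitment-to-inflation (R/I) ratio, CT-based dynamic, static and global
    lung strain, and the cohort statistics used to relate the bedside R/I to
    CT-measured recruitability. A synthetic recruitable-lung generator
    produces CT phantoms and matching ventilator traces with analytic ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
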