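Package: ichcost
Title: Hospital Cost and Length-of-Stay Modelling After Intracerebral
    Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing hospital treatment costs and length of
    stay in cohorts of spontaneous intracerebral hemorrhage (ICH)
    discharges. Classifies ICD-9-CM/ICD-10-CA diagnosis codes into
    thirteen morbidity categories, estimates dollar-scale cost effects
    from log-cost regression with heteroscedasticity-robust standard
    errors and Duan smearing retransformation, fits log-binomial
    relative-risk models for prolonged stay and in-hospital death,
    models the curvilinear cost versus length-of-stay relationship with
    restricted cubic and weekly linear splines, and runs a generational
    Monte Carlo cohort simulation. Includes a calibrated synthetic
    discharge-cohort generator so every stage can be exercised and
    validated without access to administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    sandwich,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
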