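Package: rxcohort
Title: New-User Cohorts, Comorbidity Profiles, Treatment Trajectories and
    Adherence from Pharmacy Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A drug-utilization analysis pipeline for administrative pharmacy
    dispensing data, centred on treatment-naive initiators of antidiabetic
    therapy. Implements new-user cohort selection with a wash-out period,
    index-date identification and dispensing-frequency filters; an adapted
    Rx-Risk comorbidity index mapping ATC level-2 drug classes to treated
    conditions; classification of the first treatment intensification of
    metformin initiators into add-on, switch and switch-then-discontinue
    trajectories; and medication adherence measured as the continuous
    multiple-interval measure of medication availability (CMA) from
    DDD-based days of supply. A synthetic claims generator produces
    dispensing streams and death registries with planted patient archetypes
    for validation, together with deterministic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
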