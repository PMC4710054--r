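Package: alcpolicy
Title: Appraisal of Alcohol Pricing and Availability Policies on Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A population-level simulator for appraising alcohol policies
    (minimum unit pricing, general and targeted price rises, discount
    restrictions, and availability/advertising what-ifs).  Policies act on a
    weighted transaction-level price distribution; consumption responds
    through 16x16 own- and cross-price elasticity matrices applied to
    survey-like consumption microdata; health, crime and workplace harms
    respond through calibrated relative-risk functions and the potential
    impact fraction; a ten-year age-cohort projection with a linear lag on
    chronic harms yields deaths, hospitalisations, QALYs and costs, which
    are monetised alongside retailer, duty and VAT revenue accounting.
    Includes seeded synthetic-data generators emulating the survey inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
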