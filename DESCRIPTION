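Package: prokrates
Title: Growth, Mortality and Multi-Stressor Response Analysis for Planktonic Heterotrophic Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing microcosm observations of planktonic
    heterotrophic prokaryotes into ecological rates and factorial effect
    tests. Converts epifluorescence microscopy field counts and cell
    biovolumes into abundance and biomass, radiolabelled-leucine
    scintillation counts into carbon production and cell-specific activity,
    and paired start/end states into specific instantaneous growth, net
    growth, and mortality rates. Includes balanced two-way factorial ANOVA
    with generalized omega-squared effect sizes and assumption checks,
    seawater carbonate-system speciation from total alkalinity and pH, a
    stochastic generator of complete synthetic microcosm experiments with
    known ground-truth rates, and an end-to-end pipeline producing
    publication-shaped rate and effects tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    jsonlite
Config/testthat/edition: 3
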