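Package: twosexlt
Title: Age-Stage Two-Sex Life Tables with Bootstrap Inference and
    Population Projection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for insect demography built on the age-stage, two-sex
    life-table framework. Builds age-stage survival (s_xj) and fecundity
    (f_xj) schedules from per-individual cohort life histories, solves the
    Euler-Lotka equation for the intrinsic rate of increase and derives the
    finite rate, net reproductive rate and mean generation time, computes
    age-stage life expectancy and reproductive value, estimates standard
    errors by individual-level bootstrap with a paired bootstrap test for
    treatment comparisons, and projects population size and stage structure
    under unlimited growth. Includes a calibrated synthetic cohort generator
    emulating western flower thrips (Frankliniella occidentalis) rearing
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
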