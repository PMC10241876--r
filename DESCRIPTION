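Package: cohortlife
Title: Cohort Life-Table Analysis for Insect Rearing Studies
Version: 0.1.0
Authors@R:
    person("Cohortlife", "Maintainers", email = "maintainers@cohortlife.example.org",
           role = c("aut", "cre"))
Description: Tools for female-based cohort life-table analysis of insect
    rearing experiments: individual-level rearing records (stage durations,
    fate, sex, daily fecundity) are turned into age-specific survival (lx)
    and fecundity (mx) schedules, from which the net reproductive rate (R0),
    mean generation time (T), intrinsic rate of increase (rm, via the
    Euler-Lotka equation) and finite rate of increase (lambda) are computed.
    Leave-one-out jackknife standard errors with Tukey studentized-range
    comparison across treatments, Kruskal-Wallis tests with
    Dwass-Steel-Critchlow-Fligner (DSCF) post hoc comparisons, one-way ANOVA
    with Tukey-Kramer letters, and a fully parameterised synthetic-cohort
    generator with exact analytic expectations for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
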