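Package: rgepath
Title: Path-Model Mediation and Gene-Environment Correlation for
    Intergenerational Transmission of Education
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how parental involvement and a child's
    education polygenic score jointly mediate and confound the
    intergenerational transmission of educational attainment.  Provides a
    family-structured cohort simulator with Mendelian transmission,
    assortative mating, population stratification and switchable passive or
    evocative gene-environment correlation; survey-variable coding
    (education recoding to years, additive involvement scales, Cronbach's
    alpha); a recursive linear path model with cluster-robust inference,
    indirect effects, proportions mediated and nested-model genetic and
    social confounding decomposition; residual-based correlated-effects
    correlations; between-family random-intercept and within-family
    sibling-difference estimates of gene-environment correlation; and a
    reproducible config-driven pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    sandwich,
    optparse
Config/testthat/edition: 3
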