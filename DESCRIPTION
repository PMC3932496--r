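Package: lexisurv
Title: Individual Relative Survival Analysis for Long Follow-Up Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for individual relative survival analysis of cohort
    mortality with decades of follow-up. Observed survival times are
    transformed, by integrating sex-specific national mortality rates along
    each subject's Lexis diagonal (age and calendar time advancing
    together), into an expected cumulative hazard scale on which subjects
    entering at different ages and in different eras are directly
    comparable. The transformed times are modelled by Cox or Weibull
    proportional-hazards regression with gender-by-smoking-grade
    interactions expressed as female-to-male relative risk ratios, checked
    by a Schoenfeld-residual correlation diagnostic, and inverted back to
    conditional residual-lifetime percentiles and mortality curves on the
    attained-age scale. A synthetic rate-table and cohort generator with
    known truth supports calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
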