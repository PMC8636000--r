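Package: florsel
Title: Herbivore-Mediated Phenotypic Selection on Floral Traits Across Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying herbivore-mediated phenotypic selection on
    floral traits across plant populations from paired herbivore-present /
    herbivore-exclusion experiments. Implements Lande-Arnold selection
    gradients with collinearity diagnostics, the opportunity for selection,
    treatment contrasts of selection gradients with propagated standard
    errors and ANCOVA interaction tests, folded-normal handling of
    absolute-value effect sizes, and linear-versus-quadratic meta-regression
    of selection strength on herbivory intensity by ordinary least squares
    (AIC) and by a Bayesian measurement-error model fitted with a conjugate
    Gibbs sampler (DIC). Includes a synthetic-data generator emulating the
    paired-plant multi-population study design so the full inference chain
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
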