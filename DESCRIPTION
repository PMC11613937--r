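Package: dvcost
Title: Latent Trait Modelling of Domestic Violence and Its Consequent Cost
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures domestic violence against ever-violated married women and
    the cost it imposes on them as two second-order latent traits. Seventeen
    binary spousal-violence items load on four first-order factors (economic,
    physical, psychological, sexual violence) summarized by a single Violence
    trait; eighteen binary and three-category cost items load on three factors
    (quality of life, children, economic cost) summarized by a Cost trait that
    is regressed on Violence, with optional socioeconomic covariate effects on
    Violence. Items follow two-parameter logistic and graded response models;
    estimation is marginal maximum likelihood with nested Gauss-Hermite
    quadrature and analytic gradients in compiled code. Includes a synthetic
    survey generator emulating the structure of a restricted national
    gender-based-violence survey, survey preparation rules (binary recoding,
    derived money-cost variables, eligibility filtering), a polychoric
    exploratory factor analysis stage with composite reliability and average
    variance extracted, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    statmod,
    mvtnorm,
    yaml,
    jsonlite,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    withr
Config/testthat/edition: 3
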