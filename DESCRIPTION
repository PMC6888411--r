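Package: stprev
Title: Bayesian Spatio-Temporal Disease Mapping of Prevalence with Shared
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian spatio-temporal disease-mapping models for
    non-rare binary outcomes recorded as region-by-wave binomial panels,
    such as survey-based hypertension prevalence. Implements a
    binomial-logit Besag-York-Mollie (BYM) convolution model with cubic
    B-spline global and region-specific time trends, and a two-outcome
    shared component model (SCM) in which a common spatial and
    spatio-temporal component is split between outcomes (here the two
    sexes) by time-varying weights delta_t and 1/delta_t. Spatial structure
    enters through intrinsic conditional autoregressive (ICAR) priors and a
    multivariate CAR prior on random spline coefficients; inference is by
    adaptive Metropolis-within-Gibbs MCMC with Brooks-Gelman-Rubin
    diagnostics, autocorrelation checks, DIC model comparison, DIC-guided
    forward knot selection, Moran's I screening with a permutation test,
    a prior-sensitivity harness, and a synthetic panel generator that
    emulates the structure of a multi-wave national health survey.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
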