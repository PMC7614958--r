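Package: chainmeld
Title: Chained Markov Melding for Joining Bayesian Submodels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joins chains of Bayesian submodels that share common quantities
    with their neighbours into a single coherent joint model (chained Markov
    melding).  Provides chained logarithmic, linear and dictatorial pooling of
    prior marginals, marginal replacement and assembly of the melded
    log-density, a two-stage parallel Metropolis-within-Gibbs sampler that
    recycles stage-one subposterior draws as stage-two proposals, a
    normal-approximation variant, and a worked integrated population model
    (capture-recapture, census counts and fecundity data for little owls) with
    a data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
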