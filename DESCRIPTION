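Package: copmaxent
Title: Copula and Maximum-Entropy Models of Neural Population Activity
    from Sequential Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the simultaneous activity of a population of same-type
    neurons from sequential (non-simultaneous) recordings.  Trial-to-trial
    noise dependence between spike counts is modelled with discrete bivariate
    copulas (Gumbel, Gaussian, Frank, Clayton) whose single parameter follows
    a three-parameter law of inter-cell distance; the pairwise predictions are
    then composed into a time-dependent maximum-entropy population model with
    bin-specific fields and time-shared couplings.  Includes exact
    small-system enumeration and Gibbs sampling for the population model,
    trial-shuffling controls, seeded synthetic-data generators (truncated
    Poisson marginals with latent-Gaussian distance-decaying noise
    correlations), mosaic lattice synthesis, and population-synchrony scaling
    analyses over circular patches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
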