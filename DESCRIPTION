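Package: quadassort
Title: Assortative-Mating Inference from Partner, Sibling, and In-Law Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying assortative mating with family "quad" data: one
    couple plus one full sibling of each partner. Estimates tetrachoric,
    polyserial, and Pearson correlations under a liability-threshold model by
    full-information maximum likelihood with definition-variable covariate
    adjustment; fits the joint four-person correlation structure (partner,
    sibling, sibling-in-law, co-sibling-in-law); computes the in-law inflation
    factor and a one-degree-of-freedom likelihood-ratio test of direct
    phenotypic assortment; and simulates quad populations under direct
    assortment, indirect assortment via a latent mating factor, social
    stratification, and post-formation convergence, including dichotomization
    at specified prevalences, multitrait structure, and skewed-liability
    variants. Includes prevalence descriptives, logistic-regression odds-ratio
    checks, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    numDeriv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
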