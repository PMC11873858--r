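Package: rmixtree
Title: Response-Mixture IRTree Models for Likert Scales with a Middle
    Category
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian estimation of a response-mixture IRTree model for
    Likert-scale items whose middle category can be used either as a
    genuine neutral position or as a covert non-response.  A probit
    decision tree places a non-response node (normal-ogive model with a
    common slope and item intercepts) before a graded response model for
    the informative responses; a middle-category answer can arise from
    either path, so path membership is a latent per-response mixture.
    Estimation is by Gibbs sampling with Albert-Chib data augmentation,
    with graded response model and pure IRTree baselines, deviance
    information criterion model comparison with Gauss-Hermite
    marginalization of the non-response trait, posterior summaries of
    the non-informative response share, and a parameter-recovery
    simulation framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
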