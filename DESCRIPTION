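Package: unimodal
Title: Detecting Unimodal Species-Environment Response with Generalized
    Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect unimodal (niche-type) species responses along an
    environmental gradient from presence-absence community data without
    fitting explicit quadratic response curves.  A binomial logit mixed model
    with random species intercepts and slopes and random site effects is
    fitted to the binary sites-by-species matrix; the conditional modes of
    the site effects are then regressed on the gradient, its square and the
    site species totals, and the significance of the squared term provides a
    test for unimodal response.  Includes per-species Gaussian logistic fits
    and the parameter transforms linking them to the mixed model, Whittaker
    beta-diversity descriptors, and a Gaussian-logistic community simulator
    for power and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
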