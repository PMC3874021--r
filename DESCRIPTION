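Package: saxsgp
Title: Statistical Merging of Small-Angle Scattering Profiles with Gaussian Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated merging of buffer-subtracted small-angle X-ray (or
    neutron) scattering profiles collected at different concentrations or
    exposure times. Each profile is cleaned with Bonferroni-corrected
    one-sample t-tests, fitted with a semi-parametric Gaussian process whose
    prior mean is a nested Guinier / generalized Guinier-Porod family
    (hyperparameters estimated by type-II maximum likelihood, model selection
    by Laplace-approximated Bayes factors), rescaled to a common reference,
    screened for locally incompatible regions with Welch tests against the
    fitted reference posterior, and merged into a single posterior profile
    with credible intervals and estimates of the radius of gyration and
    Porod exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
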