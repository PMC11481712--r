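Package: hrtmdose
Title: Stochastic Internal Dosimetry for Inhaled Radionuclides with the ICRP
    Human Respiratory Tract Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Committed effective dose coefficients for inhaled radionuclides
    from regional aerosol deposition in the human respiratory tract, coupled
    first-order biokinetic transport (particle clearance, dissolution,
    alimentary link, element-specific systemic model, radioactive decay),
    and sex-averaged tissue-weighted dosimetry. Uncertainty in the
    respiratory-tract parameters is propagated by latin hypercube sampling
    over eighteen published parameter distributions; the resulting dose
    coefficient sample is characterised by Kolmogorov-Smirnov distribution
    fitting and uncertainty factors, and parameter importance is ranked with
    a random-forest surrogate carrying exact tree-path Shapley attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    randomForest,
    lhs,
    fitdistrplus,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
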