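Package: rrmsim
Title: Stochastic In Silico Trials for Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multi-layer stochastic simulator of the human immune system with a
    relapsing-remitting multiple sclerosis disease layer and pluggable treatment
    layers (cladribine, ocrelizumab, interferon beta-1a, placebo). Digital
    patients with randomized HLA/MHC repertoires are generated, calibrated
    against clinical-trial relapse and lymphocytopenia targets, and run through
    in silico trials. Endpoints include MRI-detectable relapses derived from
    oligodendrocyte loss, lymphocytopenia grading from absolute lymphocyte
    counts, negative-binomial annualized relapse rates with confidence
    intervals, relative rate reductions, and Levene homogeneity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    MASS,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
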