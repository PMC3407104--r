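Package: ifnpkpd
Title: Kinetic-Dynamic Modelling of Liver-Expressed Interferon Fusion Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-mechanistic kinetic/dynamic modelling of interferon-alpha
    and interferon-alpha-apolipoprotein A-I fusion proteins expressed in situ
    in mouse liver after hydrodynamic plasmid injection. Provides the coupled
    ordinary differential equation system for hepatic transcription, transit
    compartment-delayed protein synthesis, liver-serum-brain disposition and
    turnover-type interferon-stimulated gene response; maximum-likelihood
    fitting of log-transformed concentration data with a proportional error
    model via a four-stage sequential strategy; likelihood-ratio and AIC model
    selection; derived pharmacokinetic quantities (mean transit time,
    half-life, AUC); and a synthetic-data generator that emulates the
    destructive-sampling mouse study design so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
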